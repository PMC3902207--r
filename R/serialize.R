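# Text serialization of the main artifacts (JSON containers with named
# entries, plus raster sidecars for scene fixtures).

#' Write / read a filter bank as a JSON container
#'
#' Named entries `W`, `b`, `What`, `bhat` (with dimensions) plus
#' metadata (kind, stride, sigma/gain where applicable).
#'
#' @param bank A `filter_bank`.
#' @param path Output path (`.json`).
#' @return `read_filter_bank` returns a `filter_bank`.
#' @export
write_filter_bank <- function(bank, path) {
  enc <- function(a) if (is.null(a)) NULL else
    list(dim = dim(a) %||% length(a), values = as.numeric(a))
  obj <- list(kind = bank$kind, stride = bank$stride,
              sigma = bank$sigma, gain = bank$gain,
              W = enc(bank$W), b = enc(bank$b),
              What = enc(bank$What), bhat = enc(bank$bhat))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_filter_bank
#' @export
read_filter_bank <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec <- function(e) {
    if (is.null(e) || length(e) == 0L) return(NULL)
    array(as.numeric(e$values), as.integer(e$dim))
  }
  structure(list(W = dec(obj$W), b = as.numeric(dec(obj$b)),
                 What = dec(obj$What),
                 bhat = if (is.null(obj$bhat)) NULL
                        else as.numeric(dec(obj$bhat)),
                 stride = as.integer(obj$stride), kind = obj$kind,
                 sigma = obj$sigma, gain = obj$gain %||% 1),
            class = "filter_bank")
}

#' Write / read a scene fixture
#'
#' Stores the image (PNG, clipped to `[0, 1]`), the ground-truth masks
#' as a plain-text label raster on the neuron grid (TSV), and a JSON
#' manifest with the seed and generator parameters.
#'
#' @param scene A `scene_fixture`.
#' @param dir Output directory (created if missing).
#' @return `read_scene_fixture` returns a list with `image`, `masks`
#'   and the manifest `meta` (pixel values survive the 16-bit PNG round
#'   trip only approximately).
#' @export
write_scene_fixture <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(scene$image)
  px <- array(pmin(1, pmax(0, as.numeric(scene$image))), d)
  png::writePNG(px, file.path(dir, "image.png"))
  lab <- matrix(0L, nrow(scene$masks[[1L]]$mask),
                ncol(scene$masks[[1L]]$mask))
  for (i in seq_along(scene$masks)) lab[scene$masks[[i]]$mask] <- i
  write.table(lab, file.path(dir, "masks.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(seed = scene$seed, params = scene$params,
         labels = vapply(scene$masks, `[[`, "", "label")),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_scene_fixture
#' @export
read_scene_fixture <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  img <- read_image(file.path(dir, "image.png"))
  lab <- as.matrix(read.delim(file.path(dir, "masks.tsv"),
                              header = FALSE))
  dimnames(lab) <- NULL
  masks <- lapply(seq_along(meta$labels), function(i)
    segment_mask(lab == i, meta$labels[i]))
  list(image = img, masks = masks, meta = meta)
}
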