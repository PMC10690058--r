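#' Load an image dataset from a manifest CSV
#'
#' The manifest must have columns `path`, `label` and optionally
#' `source_id` (defaulting to the file name without extension). Paths are
#' resolved relative to the manifest's directory unless absolute. Exactly
#' two classes are required, every file must exist and be readable, and
#' duplicate paths or source ids are rejected with the offending rows
#' named.
#'
#' @param path manifest CSV path (UTF-8, header required, comma-separated).
#' @return An [img_dataset()] of original (untransformed) images.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  man <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(man)))
    stopf("manifest must have columns path,label[,source_id]")
  if (anyDuplicated(man$path))
    stopf("duplicate paths in manifest: %s",
          paste(unique(man$path[duplicated(man$path)]), collapse = ", "))
  if (is.null(man$source_id))
    man$source_id <- sub("\\.[A-Za-z]+$", "", basename(man$path))
  if (anyDuplicated(man$source_id))
    stopf("duplicate source ids: %s",
          paste(unique(man$source_id[duplicated(man$source_id)]),
                collapse = ", "))
  classes <- sort(unique(man$label))
  if (length(classes) != 2L)
    stopf("exactly two classes required, found %d (%s)", length(classes),
          paste(classes, collapse = ", "))
  base <- dirname(path)
  files <- ifelse(grepl("^(/|[A-Za-z]:)", man$path), man$path,
                  file.path(base, man$path))
  missing <- !file.exists(files)
  if (any(missing))
    stopf("missing image file(s) at manifest row(s) %s: %s",
          paste(which(missing), collapse = ", "),
          paste(files[missing], collapse = ", "))
  images <- lapply(seq_len(nrow(man)), function(i) {
    px <- EBImage::readImage(files[i])
    d <- dim(EBImage::imageData(px))
    px <- if (length(d) == 2L) from_ebimage(px)
    else aperm(EBImage::imageData(px), c(2L, 1L, 3L))
    labelled_image(px, man$label[i], man$source_id[i])
  })
  img_dataset(images)
}

#' Write a dataset manifest (with transform provenance)
#'
#' Writes augmented or original images as PNGs plus an expanded manifest
#' with a `transform_chain` column (compact JSON per image).
#'
#' @param dataset an [img_dataset()].
#' @param dir output directory.
#' @return Invisibly, the manifest data frame.
#' @export
write_augmented <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(dataset$images), function(i) {
    im <- dataset$images[[i]]
    fn <- sprintf("%s_v%05d.png", im$source_id, i)
    EBImage::writeImage(as_ebimage(clamp01(im$pixels)), file.path(dir, fn))
    data.frame(path = fn, label = im$label, source_id = im$source_id,
               transform_chain = as.character(
                 jsonlite::toJSON(im$transform_chain, auto_unbox = TRUE,
                                  digits = 6L)),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
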