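#' Labelled greyscale image
#'
#' The unit of data flowing through the pipeline: a square (after
#' preprocessing) greyscale intensity matrix in `[0, 1]` together with its
#' class label, the identity of the source specimen it derives from, and the
#' ordered chain of transforms that produced it. Original images have an
#' empty `transform_chain`; every augmented variant inherits the
#' `source_id` of its parent, which is what the partitioning module uses to
#' keep variants of one specimen on one side of a train/validation split.
#'
#' @param pixels numeric matrix (rows = image rows) with values in `[0, 1]`,
#'   or an `(H, W, 3)` array for colour sources.
#' @param label class name (character scalar).
#' @param source_id identifier of the original specimen image.
#' @param transform_chain list of transform descriptors (each a list with at
#'   least `$name`).
#' @param geometry optional list of ground-truth shape parameters recorded
#'   by the synthetic generator.
#' @return An object of class `labelled_image`.
#' @export
labelled_image <- function(pixels, label, source_id,
                           transform_chain = list(), geometry = NULL) {
  if (!is.numeric(pixels)) stopf("pixels must be numeric")
  stopifnot(length(label) == 1L, length(source_id) == 1L)
  structure(
    list(pixels = pixels, label = as.character(label),
         source_id = as.character(source_id),
         transform_chain = transform_chain, geometry = geometry),
    class = "labelled_image")
}

#' @export
print.labelled_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<labelled_image %s [%dx%d] label=%s source=%s, %d transform(s)>\n",
              if (length(d) == 2L) "grey" else "colour", d[1L], d[2L],
              x$label, x$source_id, length(x$transform_chain)))
  invisible(x)
}

#' Image dataset
#'
#' An ordered collection of [labelled_image()] objects with exactly two
#' classes (once labelled data reach the modelling stages).
#'
#' @param images list of `labelled_image` objects.
#' @return An object of class `img_dataset`.
#' @export
img_dataset <- function(images) {
  stopifnot(is.list(images))
  ok <- vapply(images, inherits, logical(1L), "labelled_image")
  if (!all(ok)) stopf("all elements must be labelled_image objects")
  structure(list(images = images), class = "img_dataset")
}

#' @export
length.img_dataset <- function(x) length(x$images)

#' @export
print.img_dataset <- function(x, ...) {
  tab <- table(dataset_labels(x))
  cat(sprintf("<img_dataset: %d images; %s>\n", length(x),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Labels, source ids and subsets of a dataset
#'
#' @param dataset an [img_dataset()].
#' @return `dataset_labels()` / `dataset_ids()` return character vectors in
#'   dataset order; `dataset_subset()` returns the `img_dataset` restricted
#'   to images whose `source_id` is in `ids`.
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset$images, `[[`, character(1L), "label")
}

#' @rdname dataset_labels
#' @export
dataset_ids <- function(dataset) {
  vapply(dataset$images, `[[`, character(1L), "source_id")
}

#' @rdname dataset_labels
#' @param ids character vector of source ids to keep.
#' @export
dataset_subset <- function(dataset, ids) {
  img_dataset(dataset$images[dataset_ids(dataset) %in% ids])
}

# map of source_id -> label over unique sources
source_label_map <- function(dataset) {
  ids <- dataset_ids(dataset)
  labs <- dataset_labels(dataset)
  keep <- !duplicated(ids)
  stats::setNames(labs[keep], ids[keep])
}

# Stack a dataset into an (H, W, 1, B) array plus integer class vector.
dataset_to_array <- function(dataset, class_names) {
  B <- length(dataset)
  stopifnot(B > 0L)
  d <- dim(dataset$images[[1L]]$pixels)
  X <- array(0, c(d[1L], d[2L], 1L, B))
  for (i in seq_len(B)) X[, , 1L, i] <- dataset$images[[i]]$pixels
  y <- match(dataset_labels(dataset), class_names)
  if (anyNA(y)) stopf("labels outside class set: %s",
                      paste(setdiff(dataset_labels(dataset), class_names),
                            collapse = ", "))
  list(x = X, y = y)
}
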