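#' Single-study survival dataset
#'
#' Bundles right-censored survival outcomes with a feature matrix for one
#' study. Times must be positive; the event indicator is 1 for an observed
#' event and 0 for right censoring.
#'
#' @param time numeric vector of observed times (> 0).
#' @param event integer/numeric vector of event indicators in \{0, 1\}.
#' @param features numeric matrix, one row per subject, one column per
#'   feature. Column names are used as feature identifiers when
#'   `feature_ids` is missing.
#' @param feature_ids character vector of unique feature identifiers.
#' @param study_id label for the study.
#' @return An object of class `ms_study`.
#' @export
ms_study <- function(time, event, features, feature_ids = colnames(features),
                     study_id = "study") {
  features <- as.matrix(features)
  n <- length(time)
  if (length(event) != n || nrow(features) != n)
    stop("time, event and features must describe the same subjects")
  if (n < 2) stop("a study needs at least 2 subjects")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("all observed times must be positive and finite")
  if (!all(event %in% c(0, 1)))
    stop("event indicators must be 0 (censored) or 1 (event); found: ",
         paste(unique(event[!event %in% c(0, 1)]), collapse = ", "))
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(ncol(features)))
  if (anyDuplicated(feature_ids)) stop("feature_ids must be unique")
  if (length(feature_ids) != ncol(features))
    stop("feature_ids length must match the number of feature columns")
  colnames(features) <- feature_ids
  structure(list(time = as.numeric(time), event = as.integer(event),
                 features = features, feature_ids = feature_ids,
                 study_id = study_id),
            class = "ms_study")
}

#' @export
print.ms_study <- function(x, ...) {
  cat(sprintf("<ms_study '%s'>  n = %d subjects (%d events), p = %d features\n",
              x$study_id, length(x$time), sum(x$event), ncol(x$features)))
  invisible(x)
}

#' Multi-study survival dataset
#'
#' Aligns K single-study datasets on a shared feature index. Features are
#' matched by identifier; only identifiers present in every study are kept,
#' in the order they appear in the first study.
#'
#' @param studies list of [ms_study] objects.
#' @return An object of class `ms_data` with elements `studies` (the aligned
#'   studies) and `feature_ids`.
#' @export
ms_data <- function(studies) {
  if (!length(studies)) stop("need at least one study")
  if (!all(vapply(studies, inherits, logical(1), "ms_study")))
    stop("all elements must be ms_study objects")
  shared <- studies[[1]]$feature_ids
  for (s in studies[-1]) shared <- shared[shared %in% s$feature_ids]
  if (!length(shared)) stop("no feature identifiers shared by all studies")
  dropped <- sum(vapply(studies, function(s) length(s$feature_ids), 0L)) -
    length(studies) * length(shared)
  if (dropped > 0)
    message(sprintf("ms_data: %d study-feature columns outside the shared set dropped (p = %d kept)",
                    dropped, length(shared)))
  studies <- lapply(studies, function(s) {
    s$features <- s$features[, shared, drop = FALSE]
    s$feature_ids <- shared
    s
  })
  ids <- vapply(studies, function(s) as.character(s$study_id), "")
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  names(studies) <- ids
  structure(list(studies = studies, feature_ids = shared),
            class = "ms_data")
}

#' @export
print.ms_data <- function(x, ...) {
  cat(sprintf("<ms_data>  K = %d studies, p = %d shared features\n",
              length(x$studies), length(x$feature_ids)))
  for (s in x$studies)
    cat(sprintf("  %-12s n = %4d  events = %4d\n", s$study_id,
                length(s$time), sum(s$event)))
  invisible(x)
}

#' Number of studies / features in a multi-study dataset
#' @param data an `ms_data` object.
#' @return integer.
#' @export
n_studies <- function(data) length(data$studies)

#' @rdname n_studies
#' @export
n_features <- function(data) length(data$feature_ids)

#' Restrict a multi-study dataset to a feature subset
#'
#' @param data an `ms_data` object.
#' @param features integer indices or character identifiers.
#' @return An `ms_data` over the requested features, in the requested order.
#' @export
restrict_features <- function(data, features) {
  idx <- resolve_features(data$feature_ids, features)
  data$studies <- lapply(data$studies, function(s) {
    s$features <- s$features[, idx, drop = FALSE]
    s$feature_ids <- s$feature_ids[idx]
    s
  })
  data$feature_ids <- data$feature_ids[idx]
  data
}

resolve_features <- function(ids, features) {
  if (is.character(features)) {
    idx <- match(features, ids)
    if (anyNA(idx)) stop("unknown feature identifiers: ",
                         paste(features[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(features)
    if (any(idx < 1L | idx > length(ids))) stop("feature index out of range")
  }
  idx
}

# Sorted representation used by the compiled routines: rows ordered by
# decreasing time; risk_end[i] is the 0-based end of subject i's tie block,
# so that positions 0..risk_end[i] form the Breslow risk set {j: Y_j >= Y_i}.
study_sorted <- function(study, features = NULL) {
  ord <- order(study$time, decreasing = TRUE)
  t_sorted <- study$time[ord]
  r <- rle(t_sorted)
  risk_end <- rep.int(cumsum(r$lengths), r$lengths) - 1L
  X <- study$features
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  Xs <- X[ord, , drop = FALSE]
  list(X = Xs, Xt = t(Xs), delta = as.numeric(study$event[ord]),
       risk_end = as.integer(risk_end), ord = ord)
}

# Standardize features to zero mean / unit variance within each study.
# Returns the transformed ms_data plus the per-study scale matrices needed
# to map coefficients back to the original scale. Constant columns keep
# scale 1 (they carry no information either way).
standardize_ms <- function(data) {
  scales <- lapply(data$studies, function(s) {
    ctr <- colMeans(s$features)
    scl <- apply(s$features, 2, sd)
    scl[!is.finite(scl) | scl < 1e-12] <- 1
    list(center = ctr, scale = scl)
  })
  data$studies <- Map(function(s, sc) {
    s$features <- sweep(sweep(s$features, 2, sc$center, "-"), 2, sc$scale, "/")
    s
  }, data$studies, scales)
  attr(data, "scaling") <- scales
  data
}
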