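# Dataset container, file readers/writers, and the two generic dataset
# preparation procedures: stratified three-way survival splitting and
# per-sample quantile normalization onto a reference profile.

#' Annotated dataset: feature matrix, outcomes and cohort roles
#'
#' The universe an exhaustive signature search runs over. Holds a numeric
#' samples-by-features matrix, a per-sample outcome (a class label for
#' classification, or a survival time plus event indicator), and a
#' per-sample cohort role: `"training"`, `"validation"`, or
#' `"filtration:<name>"` (several named filtration cohorts are allowed).
#'
#' Invariants enforced at construction: every sample has exactly one role
#' and one outcome record, the matrix has no missing values, and feature
#' names are unique.
#'
#' @param matrix Numeric matrix, samples in rows (rownames = sample ids),
#'   features in columns (colnames = feature names).
#' @param outcome Data frame indexed by the same sample ids. Either a
#'   single column `label` (small integer class codes) or two columns
#'   `time` (positive) and `event` (logical, `TRUE` = event observed).
#' @param roles Character vector named by sample id with values
#'   `"training"`, `"validation"` or `"filtration:<name>"`.
#' @return An object of class `annotated_dataset`.
#' @seealso [load_dataset()], [generate_classification()],
#'   [generate_survival()]
#' @export
annotated_dataset <- function(matrix, outcome, roles) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("matrix must be a numeric matrix (samples x features)")
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("matrix needs sample ids as rownames and feature names as colnames")
  }
  if (anyDuplicated(colnames(matrix))) {
    dup <- colnames(matrix)[duplicated(colnames(matrix))][1]
    stop("duplicate feature name: ", dup)
  }
  if (anyDuplicated(rownames(matrix))) {
    dup <- rownames(matrix)[duplicated(rownames(matrix))][1]
    stop("duplicate sample id: ", dup)
  }
  if (anyNA(matrix)) {
    idx <- which(is.na(matrix), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value in matrix at sample '%s', feature '%s'",
                 rownames(matrix)[idx[1]], colnames(matrix)[idx[2]]))
  }
  samples <- rownames(matrix)
  missing_out <- setdiff(samples, rownames(outcome))
  if (length(missing_out) > 0) {
    stop("sample missing from annotation: ", missing_out[1])
  }
  missing_role <- setdiff(samples, names(roles))
  if (length(missing_role) > 0) {
    stop("sample missing a role: ", missing_role[1])
  }
  outcome <- outcome[samples, , drop = FALSE]
  roles <- roles[samples]
  task <- if ("label" %in% names(outcome)) "classification" else "survival"
  if (task == "survival") {
    if (!all(c("time", "event") %in% names(outcome))) {
      stop("outcome must have either a 'label' column or 'time' + 'event'")
    }
    if (any(outcome$time <= 0)) stop("survival times must be positive")
    outcome$event <- as.logical(outcome$event)
  } else {
    outcome$label <- as.integer(outcome$label)
  }
  bad <- !grepl("^(training|validation|filtration:.+)$", roles)
  if (any(bad)) {
    stop("invalid role '", roles[bad][1], "' for sample ",
         samples[bad][1],
         " (expected training, validation or filtration:<name>)")
  }
  structure(
    list(matrix = matrix, outcome = outcome, roles = roles, task = task),
    class = "annotated_dataset"
  )
}

#' @export
print.annotated_dataset <- function(x, ...) {
  cat(sprintf("annotated_dataset: %d samples x %d features (%s)\n",
              nrow(x$matrix), ncol(x$matrix), x$task))
  print(table(x$roles))
  invisible(x)
}

#' Names of the cohorts present in a dataset
#'
#' @param dataset An `annotated_dataset`.
#' @return Character vector of role tags in canonical order: training,
#'   then each filtration cohort (sorted by name), then validation.
#' @export
dataset_cohorts <- function(dataset) {
  r <- unique(dataset$roles)
  filt <- sort(r[startsWith(r, "filtration:")])
  c(intersect("training", r), filt, intersect("validation", r))
}

#' Restrict a dataset to the samples of one cohort
#' @noRd
cohort_view <- function(dataset, role, features = NULL) {
  idx <- which(dataset$roles == role)
  if (length(idx) == 0) stop("no samples with role '", role, "'")
  m <- dataset$matrix[idx, , drop = FALSE]
  if (!is.null(features)) m <- m[, features, drop = FALSE]
  list(matrix = m, outcome = dataset$outcome[idx, , drop = FALSE])
}

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read a feature matrix and sample annotation from delimited text
#'
#' The matrix file is samples-by-features with a header row of feature
#' names and sample ids in the first column; the annotation file maps each
#' sample to its outcome and cohort. Both files may be tab- or
#' comma-separated; the delimiter is sniffed from the header line.
#'
#' Annotation columns (case- and punctuation-insensitive names):
#' * `Sample` (or first column) — sample id;
#' * either `Class`, or `Time` + `Event` — the outcome;
#' * `Dataset` — cohort name (distinguishes multiple filtration sets);
#' * `Dataset type` — one of `training`, `filtration`, `validation`.
#'
#' @param matrix_path Path to the feature matrix.
#' @param annotation_path Path to the sample annotation.
#' @return A validated [annotated_dataset()].
#' @export
load_dataset <- function(matrix_path, annotation_path) {
  for (p in c(matrix_path, annotation_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  sep <- sniff_sep(matrix_path)
  raw <- utils::read.table(matrix_path, sep = sep, header = TRUE,
                           row.names = NULL, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (ncol(raw) < 2) stop("matrix file must have a sample id column plus features")
  sample_ids <- raw[[1]]
  feats <- colnames(raw)[-1]
  if (anyDuplicated(feats)) {
    stop("duplicate feature name in matrix header: ",
         feats[duplicated(feats)][1])
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) | !nzchar(trimws(vals)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric or empty cell at sample '%s', feature '%s'",
                 sample_ids[bad[1, 1]], feats[bad[1, 2]]))
  }
  dimnames(num) <- list(sample_ids, feats)

  ann <- utils::read.table(annotation_path, sep = sniff_sep(annotation_path),
                           header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  key <- tolower(gsub("[ ._]", "", colnames(ann)))
  pick <- function(name) {
    i <- match(name, key)
    if (is.na(i)) NULL else ann[[i]]
  }
  ann_samples <- pick("sample") %||% ann[[1]]
  missing <- setdiff(sample_ids, ann_samples)
  if (length(missing) > 0) {
    stop("annotation is missing sample: ", missing[1])
  }
  ord <- match(sample_ids, ann_samples)
  type <- tolower(pick("datasettype") %||%
                    stop("annotation needs a 'Dataset type' column"))[ord]
  dset <- pick("dataset")
  dset <- if (is.null(dset)) rep("F", length(ann_samples)) else dset
  dset <- dset[ord]
  roles <- ifelse(type == "filtration", paste0("filtration:", dset), type)
  names(roles) <- sample_ids

  cls <- pick("class")
  if (!is.null(cls)) {
    outcome <- data.frame(label = as.integer(cls[ord]),
                          row.names = sample_ids)
  } else {
    tm <- pick("time")
    ev <- pick("event")
    if (is.null(tm) || is.null(ev)) {
      stop("annotation needs either a 'Class' column or 'Time' + 'Event'")
    }
    outcome <- data.frame(time = as.numeric(tm[ord]),
                          event = as.logical(as.integer(ev[ord])),
                          row.names = sample_ids)
  }
  annotated_dataset(num, outcome, roles)
}

#' Write a dataset back to matrix + annotation files
#'
#' Inverse of [load_dataset()]: values representable exactly in decimal
#' round-trip bit-identically.
#'
#' @param dataset An `annotated_dataset`.
#' @param matrix_path,annotation_path Output paths.
#' @param sep Field delimiter, `"\t"` (default) or `","`.
#' @export
write_dataset <- function(dataset, matrix_path, annotation_path, sep = "\t") {
  m <- data.frame(Sample = rownames(dataset$matrix),
                  dataset$matrix, check.names = FALSE)
  utils::write.table(m, matrix_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  role <- dataset$roles
  type <- ifelse(startsWith(role, "filtration:"), "filtration", role)
  dname <- ifelse(startsWith(role, "filtration:"),
                  sub("^filtration:", "", role), type)
  ann <- data.frame(Sample = rownames(dataset$matrix), check.names = FALSE)
  if (dataset$task == "classification") {
    ann$Class <- dataset$outcome$label
  } else {
    ann$Time <- dataset$outcome$time
    ann$Event <- as.integer(dataset$outcome$event)
  }
  ann$Dataset <- dname
  ann[["Dataset type"]] <- type
  utils::write.table(ann, annotation_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(dataset)
}

# Largest-remainder apportionment of m samples across role proportions.
apportion <- function(m, proportions) {
  raw <- proportions * m
  base <- floor(raw)
  rem <- m - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Stratified three-way split of a survival cohort
#'
#' Assigns every sample to training, filtration or validation, stratifying
#' jointly by event status and by survival time. Within each event-status
#' group, times are binned at their quartiles; inside each (status, time
#' bin) stratum the samples are shuffled with the given seed and
#' apportioned to the three roles by largest remainder, so each stratum
#' matches the requested proportions to within one sample.
#'
#' @param dataset An `annotated_dataset` with survival outcome.
#' @param proportions Numeric length-3 vector (training, filtration,
#'   validation) summing to 1.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @param filtration_name Name for the filtration cohort tag.
#' @return The dataset with roles reassigned.
#' @export
stratified_survival_split <- function(dataset, proportions = rep(1, 3) / 3,
                                      seed = 1L,
                                      filtration_name = "filtration") {
  if (dataset$task != "survival") stop("survival outcome required")
  if (length(proportions) != 3 || abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must be three numbers summing to 1")
  }
  time <- dataset$outcome$time
  event <- dataset$outcome$event
  samples <- rownames(dataset$matrix)
  role_tags <- c("training", paste0("filtration:", filtration_name),
                 "validation")
  roles <- character(length(samples))
  names(roles) <- samples
  with_seed(seed, {
    for (ev in unique(event)) {
      in_ev <- which(event == ev)
      br <- unique(stats::quantile(time[in_ev], probs = c(0.25, 0.5, 0.75)))
      bin <- findInterval(time[in_ev], br, left.open = TRUE)
      for (b in unique(bin)) {
        stratum <- in_ev[bin == b]
        if (length(stratum) == 0) next
        counts <- apportion(length(stratum), proportions)
        shuffled <- sample(stratum)
        assign_tags <- rep(role_tags, times = counts)
        roles[shuffled] <- assign_tags
      }
    }
  })
  annotated_dataset(dataset$matrix, dataset$outcome, roles)
}

#' Per-sample quantile normalization onto a reference profile
#'
#' Maps every sample of `target` onto the quantile profile of `reference`:
#' the profile is the mean of the sorted per-sample value vectors of the
#' reference, and each target sample's values are replaced by the profile
#' values at their (average-tie) ranks, interpolating linearly when target
#' and profile lengths differ. After normalization the sorted value vector
#' of every target sample equals the reference profile, while the rank
#' order within each sample is preserved. The canonical use is porting
#' models fitted on microarray cohorts to RNA-seq cohorts: the RNA-seq
#' samples are re-expressed in microarray units before frozen models are
#' applied.
#'
#' @param target Numeric samples-by-features matrix to normalize.
#' @param reference Numeric samples-by-features matrix supplying the
#'   quantile profile; must share the feature set with `target`.
#' @return The normalized target matrix (same dimnames).
#' @export
quantile_normalize <- function(target, reference) {
  if (is.null(dim(reference)) || nrow(reference) == 0 || ncol(reference) == 0) {
    stop("reference matrix is empty")
  }
  if (!setequal(colnames(target), colnames(reference))) {
    stop("target and reference must share the feature set")
  }
  reference <- reference[, colnames(target), drop = FALSE]
  profile <- if (ncol(reference) == 1) {
    mean(reference[, 1])
  } else {
    rowMeans(apply(reference, 1, sort))
  }
  p <- length(profile)
  out <- target
  for (i in seq_len(nrow(target))) {
    x <- target[i, ]
    r <- rank(x, ties.method = "average")
    idx <- if (length(x) == 1) 1 else (r - 1) * (p - 1) / (length(x) - 1) + 1
    out[i, ] <- stats::approx(seq_len(p), profile, xout = idx,
                              rule = 2)$y
  }
  out
}
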