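#' Read DNA sequences from a FASTA file
#'
#' Reads a plain or gzip-compressed FASTA file into a tibble. Sequences are
#' uppercased, whitespace is stripped and multi-line records are joined.
#'
#' @param path Path to a FASTA file (optionally gzipped).
#' @return A tibble with columns `id` (character) and `sequence` (character),
#'   in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "acgt", "ACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  first <- character(0)
  line_no <- 0L
  repeat {
    ln <- readLines(con, n = 1L)
    line_no <- line_no + 1L
    if (length(ln) == 0L) break
    if (nzchar(trimws(ln))) {
      first <- ln
      break
    }
  }
  close(con)
  if (length(first) == 0L) {
    abort(paste0("FASTA format error: file is empty: ", path))
  }
  if (!startsWith(trimws(first), ">")) {
    abort(paste0(
      "FASTA format error at line ", line_no,
      ": expected a '>' header, got: ", substr(first, 1, 40)
    ))
  }
  seqs <- Biostrings::readBStringSet(path, format = "fasta")
  tibble::tibble(
    id = names(seqs),
    sequence = unname(toupper(gsub("\\s", "", as.character(seqs))))
  )
}

#' Write DNA sequences to a FASTA file
#'
#' @param records A tibble with columns `id` and `sequence`.
#' @param path Output path.
#' @param width Line width for wrapping sequences (default 80).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 80L) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  x <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Read a two-column id/label TSV
#'
#' @param path Path to a TSV with columns `id` and `label` (0/1). A header
#'   row is optional and detected from the column content.
#' @return A tibble with columns `id` (character) and `label` (integer).
#' @export
read_labels <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, col_types = "cc",
                       progress = FALSE)
  if (nrow(x) > 0 &&
      identical(unname(tolower(unlist(x[1, ]))), c("id", "label"))) {
    x <- x[-1, ]
  }
  lab <- suppressWarnings(as.integer(x[[2]]))
  if (anyNA(lab)) {
    abort("labels TSV: non-integer label values")
  }
  tibble::tibble(id = x[[1]], label = lab)
}

#' Attach binary labels to sequence records
#'
#' Joins a label table onto sequence records and validates the result:
#' unique ids, labels in \{0, 1\}, non-empty sequences. As a convenience,
#' labels may instead be parsed from a trailing `|label=0/1` token in the
#' FASTA id when `labels` is `NULL`.
#'
#' @param records A tibble with columns `id` and `sequence`.
#' @param labels A tibble with columns `id` and `label`, or `NULL` to parse
#'   `|label=` tokens from the ids.
#' @return A labelled dataset: a tibble with columns `id`, `sequence`,
#'   `label`.
#' @export
attach_labels <- function(records, labels = NULL) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  if (is.null(labels)) {
    m <- regmatches(records$id, regexpr("\\|label=[01]$", records$id))
    if (length(m) != nrow(records)) {
      abort("attach_labels: labels is NULL and not every id carries a '|label=0/1' token")
    }
    out <- tibble::tibble(
      id = sub("\\|label=[01]$", "", records$id),
      sequence = records$sequence,
      label = as.integer(sub("\\|label=", "", m))
    )
  } else {
    if (anyDuplicated(records$id) || anyDuplicated(labels$id)) {
      abort("attach_labels: duplicate id(s) in records or labels")
    }
    missing <- setdiff(records$id, labels$id)
    if (length(missing) > 0) {
      abort(paste0(
        "attach_labels: no label for id(s): ",
        paste(head(missing, 5), collapse = ", "),
        if (length(missing) > 5) paste0(" (and ", length(missing) - 5, " more)")
      ))
    }
    out <- dplyr::left_join(records, labels, by = "id")
  }
  validate_dataset(out)
  out
}

validate_dataset <- function(data, require_split = FALSE) {
  stopifnot(is.data.frame(data))
  need <- c("id", "sequence", "label")
  if (!all(need %in% names(data))) {
    abort(paste0("dataset must have columns ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(data$id)) {
    abort(paste0("duplicate record id(s): ",
                 paste(head(unique(data$id[duplicated(data$id)]), 5), collapse = ", ")))
  }
  if (!all(data$label %in% c(0L, 1L))) {
    abort("labels must be exactly 0 or 1")
  }
  if (any(!nzchar(data$sequence))) {
    abort("sequences must be non-empty")
  }
  if (require_split) {
    if (!"split" %in% names(data) || anyNA(data$split) ||
        !all(data$split %in% c("train", "validation", "test"))) {
      abort("dataset must have a 'split' column covering every record with train/validation/test")
    }
  }
  invisible(data)
}

#' Partition a labelled dataset into train/validation/test
#'
#' Assigns every record to exactly one of train, validation or test. The
#' validation and test splits get `floor(fraction * n)` records each and
#' train takes the remainder. Assignment is stratified by label so that a
#' balanced input yields balanced splits (each split within one record of
#' the input's class proportion), and is deterministic under `seed`.
#'
#' @param data A labelled dataset (columns `id`, `sequence`, `label`).
#' @param fractions Numeric length-3 vector `(train, validation, test)`;
#'   all positive, summing to 1.
#' @param seed Integer seed controlling the (stratified) random assignment.
#' @return `data` with an added `split` column.
#' @examples
#' d <- tibble::tibble(id = paste0("s", 1:10),
#'                     sequence = strrep("ACGT", 5),
#'                     label = rep(0:1, 5))
#' table(split_dataset(d, seed = 1)$split)
#' @export
split_dataset <- function(data, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  validate_dataset(data)
  if (length(fractions) != 3 || any(fractions <= 0)) {
    abort("fractions must be three positive numbers (train, validation, test)")
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    abort("fractions must sum to 1")
  }
  n <- nrow(data)
  quota <- c(
    validation = floor(fractions[2] * n),
    test = floor(fractions[3] * n)
  )
  quota <- c(train = n - sum(quota), quota)

  # Per-label targets for validation and test by floor + largest remainder,
  # matching the global quotas exactly; train absorbs the rest per label.
  labs <- sort(unique(data$label))
  n_g <- vapply(labs, function(g) sum(data$label == g), integer(1))
  alloc <- matrix(0L, nrow = length(labs), ncol = 3,
                  dimnames = list(as.character(labs),
                                  c("train", "validation", "test")))
  for (sp in c("validation", "test")) {
    ideal <- n_g * quota[[sp]] / n
    base <- floor(ideal)
    deficit <- quota[[sp]] - sum(base)
    if (deficit > 0) {
      ord <- order(ideal - base, n_g, decreasing = TRUE)
      base[ord[seq_len(deficit)]] <- base[ord[seq_len(deficit)]] + 1
    }
    alloc[, sp] <- as.integer(base)
  }
  alloc[, "train"] <- n_g - alloc[, "validation"] - alloc[, "test"]
  if (any(alloc < 0)) {
    abort("split_dataset: a label stratum is too small for the requested fractions")
  }

  split <- character(n)
  with_seed(seed, {
    for (i in seq_along(labs)) {
      idx <- which(data$label == labs[i])
      idx <- sample(idx)
      sp <- rep(c("train", "validation", "test"), times = alloc[i, ])
      split[idx] <- sp
    }
  })
  data$split <- split
  validate_dataset(data, require_split = TRUE)
  data
}

#' Write a labelled dataset to FASTA + TSV sidecars
#'
#' Writes `<prefix>.fa` (sequences), `<prefix>_labels.tsv` (`id<TAB>label`)
#' and, if a `split` column is present, `<prefix>_partition.tsv`
#' (`id<TAB>split`) so a run can be reproduced from its files.
#'
#' @param data A labelled dataset.
#' @param prefix Output path prefix.
#' @return A character vector of the files written, invisibly.
#' @export
write_dataset <- function(data, prefix) {
  validate_dataset(data)
  files <- paste0(prefix, c(".fa", "_labels.tsv"))
  write_fasta(data, files[1])
  readr::write_tsv(data[, c("id", "label")], files[2], col_names = TRUE,
                   progress = FALSE)
  if ("split" %in% names(data)) {
    f <- paste0(prefix, "_partition.tsv")
    readr::write_tsv(data[, c("id", "split")], f, col_names = TRUE,
                     progress = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}

#' Read a labelled dataset written by [write_dataset()]
#'
#' @param prefix Path prefix used by [write_dataset()].
#' @return A labelled dataset tibble, with `split` if a partition manifest
#'   exists beside the FASTA.
#' @export
read_dataset <- function(prefix) {
  records <- read_fasta(paste0(prefix, ".fa"))
  labels <- read_labels(paste0(prefix, "_labels.tsv"))
  data <- attach_labels(records, labels)
  part <- paste0(prefix, "_partition.tsv")
  if (file.exists(part)) {
    p <- readr::read_tsv(part, col_types = "cc", progress = FALSE)
    data <- dplyr::left_join(data, p, by = "id")
    validate_dataset(data, require_split = TRUE)
  }
  data
}
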