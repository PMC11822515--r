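#' NOEC endpoint records and class assignment
#'
#' Reproductive no-observed-effect concentrations (NOEC, mg compound per kg
#' soil) arrive either as real values or as typed intervals. A record is
#' converted to a binary class at a breakpoint (default 100 mg/kg, the
#' boundary of the least-harmful category): compounds with NOEC below the
#' breakpoint are toxic, at or above it nontoxic, and intervals that
#' straddle the breakpoint carry too little information and are discarded.
#'
#' @param compound_id Compound identifier.
#' @param value Real NOEC value in mg/kg (real records).
#' @param lower,upper Interval bounds in mg/kg; `upper` may be `Inf`.
#' @param lower_closed,upper_closed Logical; whether each bound is included.
#' @return An object of class `noec_record`.
#' @export
noec_record <- function(compound_id, value = NULL, lower = NULL,
                        upper = NULL, lower_closed = FALSE,
                        upper_closed = FALSE) {
  if (!is.null(value)) {
    if (!is.numeric(value) || value < 0)
      abort_config("noec_record: real NOEC must be >= 0 (got %s)", value)
    rec <- list(compound_id = compound_id, kind = "real", value = value)
  } else {
    if (is.null(lower) || is.null(upper))
      abort_config("noec_record: interval records need lower and upper")
    if (!(lower < upper))
      abort_config("noec_record: need lower < upper (got [%s, %s])",
                   lower, upper)
    if (lower < 0)
      abort_config("noec_record: lower bound must be >= 0")
    rec <- list(compound_id = compound_id, kind = "interval",
                lower = lower, upper = upper,
                lower_closed = isTRUE(lower_closed),
                upper_closed = isTRUE(upper_closed))
  }
  structure(rec, class = "noec_record")
}

#' Parse a NOEC value from its text form
#'
#' Grammar (mg/kg): a plain number (`"50"`), `"<U"` for an interval
#' (0, U) open at both ends, `">L"` for (L, Inf), `">L-U"` for (L, U]
#' (open below, closed above), and `"<A-inf"` for a record whose value is
#' only known to lie somewhere in (0, Inf) — the fully uninformative
#' dialect, discarded at any breakpoint. Intervals may also be supplied as
#' JSON objects `{"lower":, "upper":, "lower_closed":, "upper_closed":}`
#' via [noec_record()].
#'
#' @param text Character scalar.
#' @param compound_id Identifier to attach.
#' @return A `noec_record`.
#' @examples
#' parse_noec(">0-10", "a")   # (0, 10]  -> toxic
#' parse_noec("<100", "b")    # (0, 100) -> toxic
#' parse_noec(">100", "c")    # (100, Inf) -> nontoxic
#' @export
parse_noec <- function(text, compound_id = NA_character_) {
  s <- gsub("[[:space:]]", "", as.character(text))
  num <- "([0-9]+\\.?[0-9]*)"
  if (grepl(paste0("^", num, "$"), s)) {
    return(noec_record(compound_id, value = as.numeric(s)))
  }
  if (grepl(paste0("^<", num, "-[Ii]nf$"), s)) {
    return(noec_record(compound_id, lower = 0, upper = Inf))
  }
  if (grepl(paste0("^>", num, "-", num, "$"), s)) {
    m <- regmatches(s, regexec(paste0("^>", num, "-", num, "$"), s))[[1L]]
    return(noec_record(compound_id, lower = as.numeric(m[2L]),
                       upper = as.numeric(m[3L]), upper_closed = TRUE))
  }
  if (grepl(paste0("^>", num, "$"), s)) {
    return(noec_record(compound_id, lower = as.numeric(sub("^>", "", s)),
                       upper = Inf))
  }
  if (grepl(paste0("^<", num, "$"), s)) {
    return(noec_record(compound_id, lower = 0,
                       upper = as.numeric(sub("^<", "", s))))
  }
  abort_config("parse_noec: unsupported NOEC dialect '%s'", text)
}

#' Convert a NOEC record to a binary class
#'
#' Real values below the breakpoint map to `"toxic"`, at or above it to
#' `"nontoxic"`. Intervals map by containment: an interval lying entirely
#' below the breakpoint is toxic, entirely at or above it nontoxic, and
#' one that straddles the breakpoint (including an interval whose closed
#' upper bound equals the breakpoint) is `"discard"`. This reproduces the
#' full published rule set, e.g. (0, 10] toxic, (10, 100] discard,
#' (100, Inf) nontoxic, (0, 100) toxic, (0, Inf) discard at 100 mg/kg.
#'
#' @param record A `noec_record`.
#' @param breakpoint Class boundary in mg/kg (default 100).
#' @return One of `"toxic"`, `"nontoxic"`, `"discard"`.
#' @export
assign_class <- function(record, breakpoint = 100) {
  if (!inherits(record, "noec_record"))
    abort_config("assign_class: not a noec_record")
  if (record$kind == "real") {
    return(if (record$value < breakpoint) "toxic" else "nontoxic")
  }
  lo <- record$lower
  up <- record$upper
  # every attainable value < breakpoint?
  if (up < breakpoint || (up == breakpoint && !record$upper_closed))
    return("toxic")
  # every attainable value >= breakpoint? (an open bound at lo == breakpoint
  # still means all values exceed it)
  if (lo >= breakpoint) return("nontoxic")
  "discard"
}

#' Assign classes to many records
#'
#' @param records List of `noec_record`s.
#' @param breakpoint Class boundary in mg/kg.
#' @return Character vector of labels, one per record.
#' @export
assign_classes <- function(records, breakpoint = 100) {
  vapply(records, assign_class, character(1), breakpoint = breakpoint)
}

#' Split off an external test set
#'
#' Random (optionally class-stratified) sampling of `test_size` compounds
#' into an external validation set; the remainder is the modeling set.
#'
#' @param dm A labelled `descriptor_matrix`.
#' @param test_size Number of compounds to set aside.
#' @param seed Integer seed.
#' @param stratified If `TRUE`, sample proportionally within each class.
#' @return List with `modeling` and `test` descriptor matrices.
#' @export
split_dataset <- function(dm, test_size, seed, stratified = FALSE) {
  n <- nrow(dm$x)
  if (test_size >= n)
    abort_config("split_dataset: test_size %d >= n %d", test_size, n)
  idx <- with_seed(seed, {
    if (stratified && !is.null(dm$labels)) {
      per_class <- round(test_size * table(dm$labels) / n)
      # adjust rounding drift on the larger class
      per_class[1L] <- test_size - sum(per_class[-1L])
      unlist(lapply(levels(dm$labels), function(cl) {
        pool <- which(dm$labels == cl)
        sample(pool, per_class[[cl]])
      }), use.names = FALSE)
    } else if (test_size > 0) {
      sample.int(n, test_size)
    } else {
      integer(0)
    }
  })
  list(modeling = dm[setdiff(seq_len(n), idx), ],
       test = dm[idx, ])
}

#' Resample a modeling set into training and validation parts
#'
#' An 80/20 (by default) random partition, redrawn with a fresh seed every
#' generation of the genetic search so no single split is overfit.
#'
#' @param dm A `descriptor_matrix`.
#' @param train_fraction Proportion in (0, 1) for the training part.
#' @param seed Integer seed.
#' @return List with `train` and `val` descriptor matrices;
#'   `nrow(train) == floor(train_fraction * n)`.
#' @export
resample_train_val <- function(dm, train_fraction = 0.8, seed) {
  if (!(train_fraction > 0 && train_fraction < 1))
    abort_config("resample_train_val: train_fraction must be in (0,1)")
  n <- nrow(dm$x)
  n_train <- floor(train_fraction * n)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = dm[idx, ], val = dm[setdiff(seq_len(n), idx), ])
}

#' Balance classes by random under-sampling
#'
#' All minority-class compounds are retained; the majority class is
#' reduced to a seeded random subset of the same size, giving a 1:1 class
#' ratio before model fitting.
#'
#' @param dm A labelled `descriptor_matrix` containing both classes.
#' @param seed Integer seed.
#' @return A balanced `descriptor_matrix`.
#' @export
under_sample <- function(dm, seed) {
  if (is.null(dm$labels)) abort_config("under_sample: no labels attached")
  counts <- class_counts(dm)
  if (any(counts == 0))
    abort_config("under_sample: class '%s' absent, cannot balance",
                 names(counts)[counts == 0][1L])
  minority <- names(counts)[which.min(counts)]
  majority <- setdiff(names(counts), minority)
  keep_min <- which(dm$labels == minority)
  pool_maj <- which(dm$labels == majority)
  keep_maj <- with_seed(seed, sample(pool_maj, counts[[minority]]))
  dm[sort(c(keep_min, keep_maj)), ]
}

#' Jaccard similarity of two binary fingerprints
#'
#' Used in structure curation: identifiers of the same compound must yield
#' coinciding circular-fingerprint Jaccard indices.
#'
#' @param fp_a,fp_b Binary (0/1 or logical) vectors of equal length.
#' @return `|intersection| / |union|` of the set bits, in `[0, 1]`.
#' @export
jaccard_similarity <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b))
    abort_config("jaccard_similarity: fingerprint lengths differ (%d vs %d)",
                 length(fp_a), length(fp_b))
  a <- as.logical(fp_a)
  b <- as.logical(fp_b)
  un <- sum(a | b)
  if (un == 0)
    abort_config("jaccard_similarity: both fingerprints empty; undefined")
  sum(a & b) / un
}

#' Validity check for a compound's structural identifiers
#'
#' A structure is accepted when more than two distinct identifiers are
#' available and the fingerprints they resolve to all coincide (pairwise
#' Jaccard similarity of 1).
#'
#' @param fingerprints List of binary fingerprint vectors, one per
#'   identifier.
#' @return Logical scalar.
#' @export
identifiers_concordant <- function(fingerprints) {
  if (length(fingerprints) <= 2) return(FALSE)
  for (i in seq_along(fingerprints)[-1L]) {
    if (jaccard_similarity(fingerprints[[1L]], fingerprints[[i]]) < 1)
      return(FALSE)
  }
  TRUE
}
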