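# Consensus 3-state secondary-structure annotation: majority voting over
# predictor outputs, segment extraction and segmentation comparison. This is
# the layer that turns a stack of per-residue H/E/C strings (from e.g.
# PSIPRED/JPRED-class predictors, reduced to 3 states upstream) into the
# helix/strand segment map of a sequence.

SS3_STATES <- c("H", "E", "C")

split_states <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

#' Majority-vote consensus of secondary-structure predictions
#'
#' Per residue, the state with strictly the most votes wins; any tie for the
#' maximum falls back to coil, i.e. structure is never invented on a tie
#' (so two predictors voting H and E yield C).
#'
#' @param predictions character vector (>= 2) of equal-length strings over
#'   H/E/C, as returned by [read_predictions()].
#' @return object of class `consensus_ss`: list with `states` (consensus
#'   string), `votes` (3 x n matrix of counts, rows H/E/C) and `n_predictors`.
#' @examples
#' majority_vote(c("HHHC", "HHHC", "CCCC"))$states  # "HHHC"
#' @export
majority_vote <- function(predictions) {
  predictions <- as.character(predictions)
  if (length(predictions) < 2L)
    stop("consensus requires at least 2 predictors")
  lens <- nchar(predictions)
  if (length(unique(lens)) != 1L)
    stop("predictions have unequal lengths: ", paste(lens, collapse = ", "))
  chars <- vapply(predictions, split_states,
                  character(lens[1L]), USE.NAMES = FALSE)
  if (!all(chars %in% SS3_STATES))
    stop("predictions may contain only H, E, C")
  chars <- matrix(chars, nrow = lens[1L])  # residues x predictors
  votes <- vapply(SS3_STATES, function(s) rowSums(chars == s),
                  numeric(lens[1L]))
  votes <- t(matrix(votes, ncol = 3L, dimnames = list(NULL, SS3_STATES)))
  # a state wins only with strictly the most votes; any tie for the maximum
  # falls back to coil (conservative: never invent structure on a tie)
  win <- apply(votes, 2L, function(v) {
    w <- SS3_STATES[v == max(v)]
    if (length(w) == 1L) w else "C"
  })
  structure(list(states = paste(win, collapse = ""), votes = votes,
                 n_predictors = length(predictions)),
            class = "consensus_ss")
}

#' @export
print.consensus_ss <- function(x, ...) {
  cat("consensus_ss:", nchar(x$states), "residues,",
      x$n_predictors, "predictors\n")
  cat(x$states, "\n")
  invisible(x)
}

as_state_string <- function(x) {
  if (inherits(x, "consensus_ss")) x$states else as.character(x)[1L]
}

#' Extract contiguous secondary-structure segments
#'
#' Maximal runs of a target state, reported as 1-based inclusive residue
#' coordinates. The default `min_length` of 4 for helices corresponds to one
#' full helical turn (the shortest helix worth reporting).
#'
#' @param annotation a `consensus_ss` object or any H/E/C state string.
#' @param state target state, one of `"H"`, `"E"`, `"C"`.
#' @param min_length discard runs shorter than this (>= 1).
#' @param offset residue number of the first position minus one; segments are
#'   reported in `offset + position` coordinates (default 0, i.e. 1-based).
#' @return data frame with columns `state`, `start`, `end` (possibly 0 rows),
#'   ascending in `start`.
#' @examples
#' extract_segments("CCHHHHCC", "H", min_length = 2)  # one segment 3..6
#' @export
extract_segments <- function(annotation, state = "H", min_length = 4L,
                             offset = 0L) {
  stopifnot(state %in% SS3_STATES, min_length >= 1L)
  s <- split_states(as_state_string(annotation))
  r <- rle(s == state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  data.frame(state = rep(state, sum(keep)),
             start = starts[keep] + offset, end = ends[keep] + offset,
             stringsAsFactors = FALSE)
}

segments_to_states <- function(segments, range) {
  s <- rep("C", range[2L] - range[1L] + 1L)
  for (i in seq_len(nrow(segments))) {
    pos <- seq.int(segments$start[i], segments$end[i]) - range[1L] + 1L
    if (any(pos < 1L | pos > length(s)))
      stop("segment ", segments$start[i], "-", segments$end[i],
           " outside residue range ", range[1L], "-", range[2L])
    s[pos] <- segments$state[i]
  }
  s
}

#' Compare two segmentations
#'
#' Residue-level comparison of two segment sets over the same residue range:
#' per-state Jaccard index (overlap / union of residues carrying that state)
#' and the 3 x 3 residue confusion matrix. Residues not covered by any
#' segment count as coil.
#'
#' @param a,b segment data frames as returned by [extract_segments()]
#'   (columns `state`, `start`, `end`); may mix states.
#' @param range inclusive residue range `c(first, last)` both segmentations
#'   live on. Defaults to the span of `a` and `b` jointly.
#' @return list with `jaccard` (named numeric, states present in either
#'   segmentation; 1 when both sets of residues coincide, 0 when disjoint),
#'   `confusion` (3 x 3 matrix, rows = `a`, cols = `b`) and `agreement`
#'   (fraction of residues with identical state).
#' @export
compare_segmentations <- function(a, b, range = NULL) {
  if (is.null(range)) {
    lo <- min(c(a$start, b$start))
    hi <- max(c(a$end, b$end))
    range <- c(lo, hi)
  }
  sa <- segments_to_states(a, range)
  sb <- segments_to_states(b, range)
  confusion <- table(factor(sa, SS3_STATES), factor(sb, SS3_STATES))
  confusion <- unclass(confusion)
  present <- SS3_STATES[SS3_STATES %in% c(a$state, b$state)]
  jac <- vapply(present, function(s) {
    inter <- sum(sa == s & sb == s)
    uni <- sum(sa == s | sb == s)
    if (uni == 0) NA_real_ else inter / uni
  }, numeric(1))
  list(jaccard = jac, confusion = confusion,
       agreement = mean(sa == sb))
}

#' Write a consensus annotation as TSV
#'
#' One row per residue: index, per-state vote counts, consensus state.
#' @param x a `consensus_ss` object.
#' @param path output path.
#' @param offset residue numbering offset (see [extract_segments()]).
#' @return `path`, invisibly.
#' @export
write_consensus_tsv <- function(x, path, offset = 0L) {
  stopifnot(inherits(x, "consensus_ss"))
  n <- nchar(x$states)
  df <- data.frame(residue = seq_len(n) + offset,
                   votes_H = x$votes["H", ], votes_E = x$votes["E", ],
                   votes_C = x$votes["C", ],
                   consensus = split_states(x$states))
  write_report_tsv(df, path, meta = list(n_predictors = x$n_predictors,
                                         tie_break = "tie -> C"))
}
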