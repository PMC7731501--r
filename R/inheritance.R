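#' Pairwise outcome of a differential-expression comparison
#'
#' Compact representation used by the inheritance classifier: "none" (not
#' significant), "first_higher" or "second_higher" (significant, with the
#' named member of the comparison more highly expressed). A direction
#' without significance is contradictory and rejected.
#'
#' @param significant logical flag.
#' @param direction "none", "first_higher" or "second_higher".
#' @return outcome string.
#' @export
pairwise_outcome <- function(significant, direction = "none") {
  direction <- match.arg(direction, c("none", "first_higher", "second_higher"))
  if (significant && direction == "none")
    stop("significant outcome needs a direction")
  if (!significant && direction != "none")
    stop("direction without significance is contradictory")
  direction
}

#' Classify one transcript's inheritance mode from three pairwise outcomes
#'
#' Decision table over the comparisons parentA vs parentB (\code{ab}),
#' parentA vs hybrid (\code{ah}) and parentB vs hybrid (\code{bh}), each an
#' outcome string as produced by [pairwise_outcome()]:
#' \itemize{
#'   \item conserved: none of the three significant;
#'   \item transgressive_up / _down: hybrid significantly higher / lower
#'     than both parents;
#'   \item additive: hybrid significantly higher than one parent and lower
#'     than the other;
#'   \item dominantA: hybrid indistinguishable from parent A but
#'     significantly different from parent B; dominantB symmetric;
#'   \item ambiguous: the remaining combination (parents differ while the
#'     hybrid matches both).
#' }
#'
#' @param ab,ah,bh outcome strings ("none", "first_higher",
#'   "second_higher"); vectors are classified elementwise.
#' @return character vector of modes.
#' @export
classify_transcript <- function(ab, ah, bh) {
  ok <- c("none", "first_higher", "second_higher")
  if (!all(ab %in% ok & ah %in% ok & bh %in% ok))
    stop("outcomes must be one of: ", paste(ok, collapse = ", "))
  n <- max(length(ab), length(ah), length(bh))
  ab <- rep_len(ab, n); ah <- rep_len(ah, n); bh <- rep_len(bh, n)
  h_vs_a <- ah  # second member is the hybrid
  h_vs_b <- bh
  mode <- rep("ambiguous", n)
  mode[h_vs_a == "none" & h_vs_b == "none" & ab == "none"] <- "conserved"
  mode[h_vs_a == "second_higher" & h_vs_b == "second_higher"] <- "transgressive_up"
  mode[h_vs_a == "first_higher" & h_vs_b == "first_higher"] <- "transgressive_down"
  mode[(h_vs_a == "second_higher" & h_vs_b == "first_higher") |
       (h_vs_a == "first_higher" & h_vs_b == "second_higher")] <- "additive"
  mode[h_vs_a == "none" & h_vs_b != "none"] <- "dominantA"
  mode[h_vs_a != "none" & h_vs_b == "none"] <- "dominantB"
  mode
}

# de_result table -> outcome strings for the transcripts requested
.outcomes_from_de <- function(de, transcripts) {
  tab <- de$table[match(transcripts, de$table$transcript), ]
  ifelse(!tab$is_DET, "none",
         ifelse(tab$logFC > 0, "second_higher", "first_higher"))
}

#' Classify a hybrid zone's transcripts from three DE results
#'
#' Restricts to transcripts expressed in all three comparisons, derives the
#' pairwise outcomes from the DET calls, applies [classify_transcript()] and
#' tallies modes (transgressive kept split into up and down).
#'
#' @param de_ab DE result for parentA vs parentB.
#' @param de_ah DE result for parentA vs hybrid (hybrid second).
#' @param de_bh DE result for parentB vs hybrid (hybrid second).
#' @return list with \code{calls} (data.frame transcript, mode, ab, ah, bh)
#'   and \code{summary} (data.frame mode, n covering all modes plus
#'   ambiguous, with a transgressive_total attribute).
#' @export
classify_zone <- function(de_ab, de_ah, de_bh) {
  universe <- Reduce(intersect, list(de_ab$table$transcript,
                                     de_ah$table$transcript,
                                     de_bh$table$transcript))
  if (length(universe) == 0) stop("comparisons share no expressed transcripts")
  ab <- .outcomes_from_de(de_ab, universe)
  ah <- .outcomes_from_de(de_ah, universe)
  bh <- .outcomes_from_de(de_bh, universe)
  mode <- classify_transcript(ab, ah, bh)
  calls <- data.frame(transcript = universe, mode = mode,
                      ab = ab, ah = ah, bh = bh,
                      row.names = NULL, stringsAsFactors = FALSE)
  list(calls = calls, summary = inheritance_summary(mode))
}

#' Tally inheritance-mode calls
#'
#' @param modes character vector of mode calls.
#' @return data.frame (mode, n) over all recognized modes plus ambiguous;
#'   the total transgressive count (up + down) is attached as attribute
#'   \code{transgressive_total}.
#' @export
inheritance_summary <- function(modes) {
  levels <- c(inheritance_modes, "ambiguous")
  n <- vapply(levels, function(m) sum(modes == m), integer(1))
  out <- data.frame(mode = levels, n = n, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "transgressive_total") <-
    n[["transgressive_up"]] + n[["transgressive_down"]]
  out
}
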