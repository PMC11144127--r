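# Packaged reconstructions of the study's published summary tables
# (32 raters x 14 polyps; size estimates for 6 polyps). See
# inst/extdata/README.md for provenance notes.

#' Published per-polyp vote and confidence table
#'
#' The packaged reconstruction of the study's polyp-by-polyp summary:
#' pathology, majority answer and share, Likert confidence frequency
#' counts, and the printed mean Likert score, for 14 polyps judged by 32
#' raters.
#'
#' @return `data.frame` with one row per polyp.
#' @export
study_vote_table <- function() {
  path <- system.file("extdata", "study_polyp_votes.csv",
                      package = "fluoroperf", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published lesion size-estimation table
#'
#' Mean size estimate (with range) versus actual excisional pathology size
#' for the 6 polyps where raters estimated size. `fully_visible` marks
#' lesions wholly visible in a single camera view.
#'
#' @return `data.frame` with one row per measured polyp.
#' @export
study_size_table <- function() {
  path <- system.file("extdata", "study_polyp_sizes.csv",
                      package = "fluoroperf", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Agreement counts reconstructed from the published vote shares
#'
#' Rebuilds the 14 x 2 benign/cancer vote count matrix from the majority
#' percentages: the majority answer gets `round(pct * n / 100)` votes, the
#' other category the complement; the evenly split polyp is n/2 each.
#'
#' @param votes The vote table (default [study_vote_table()]).
#' @param n_raters Panel size (default 32).
#' @return An [agreement_counts()] matrix (items x benign/cancer).
#' @export
study_agreement_counts <- function(votes = study_vote_table(),
                                   n_raters = 32L) {
  maj_n <- round(votes$majority_pct * n_raters / 100)
  benign <- ifelse(votes$majority_answer == "benign", maj_n,
                   ifelse(votes$majority_answer == "cancer",
                          n_raters - maj_n, n_raters / 2))
  m <- cbind(benign = benign, cancer = n_raters - benign)
  rownames(m) <- votes$polyp_id
  agreement_counts(m)
}

#' Expand the vote table to a long pseudo-rater table
#'
#' Converts the reconstructed per-polyp vote counts into a long
#' rater x polyp table (pseudo rater ids; individual raters' answer
#' patterns across polyps are NOT recoverable from the published
#' marginals, so only polyp-level analyses — majority decisions,
#' agreement, Likert tables — are meaningful on this expansion).
#'
#' @param votes The vote table (default [study_vote_table()]).
#' @param n_raters Panel size (default 32).
#' @return Long `data.frame` with `rater_id`, `polyp_id`, `answer`,
#'   `confidence`, `truth`.
#' @export
study_long_table <- function(votes = study_vote_table(), n_raters = 32L) {
  counts <- study_agreement_counts(votes, n_raters)
  rows <- lapply(seq_len(nrow(votes)), function(i) {
    answers <- rep(c("benign", "cancer"), c(counts[i, "benign"],
                                            counts[i, "cancer"]))
    conf <- rep(1:5, as.integer(votes[i, paste0("conf_", 1:5)]))
    data.frame(rater_id = sprintf("S%02d", seq_len(n_raters)),
               polyp_id = votes$polyp_id[i],
               answer = answers,
               confidence = conf,
               truth = votes$pathology[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
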