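#' Parameters of the synthetic rater-response model
#'
#' A Rasch-style item-response model for multi-rater lesion judgement:
#' rater `r` answers item `i` correctly with probability
#' `plogis(skill[r] - difficulty[i])`. Reported Likert confidence (1-5) is
#' a monotone function of the same signed margin `skill - difficulty`, so
#' well-matched rater/item pairs report higher confidence.
#'
#' @param n_raters Number of raters.
#' @param n_items Number of polyps judged by every rater.
#' @param difficulty Per-item difficulty on the logit scale (length
#'   `n_items`, recycled if scalar).
#' @param skill Per-rater skill on the logit scale (length `n_raters`,
#'   recycled if scalar).
#' @param truth Per-item truth labels, `"benign"`/`"cancer"`; default
#'   alternates to a balanced panel.
#' @param grades Per-rater grade, recycled over
#'   `c("consultant", "late_training", "middle_training")`.
#' @param confidence_breaks Cut points on `skill - difficulty` mapping the
#'   margin to Likert levels 1..5 (4 increasing values).
#' @param confidence_noise_sd Gaussian jitter added to the margin before
#'   cutting, so confidence is stochastic but centred on the link.
#' @param seed RNG seed.
#' @return A `rater_model_params` object.
#' @export
rater_model_params <- function(n_raters = 32, n_items = 14,
                               difficulty = 0, skill = 0,
                               truth = NULL, grades = NULL,
                               confidence_breaks = c(-2, -0.5, 0.5, 2),
                               confidence_noise_sd = 1,
                               seed = 1L) {
  assert_number(n_raters, "n_raters", lower = 1)
  assert_number(n_items, "n_items", lower = 1)
  difficulty <- rep_len(as.numeric(difficulty), n_items)
  skill <- rep_len(as.numeric(skill), n_raters)
  if (is.null(truth)) truth <- rep_len(c("benign", "cancer"), n_items)
  assert_that(length(truth) == n_items && all(truth %in% c("benign", "cancer")),
              "`truth` must give benign/cancer for each of %d items", n_items)
  if (is.null(grades))
    grades <- rep_len(c("consultant", "late_training", "middle_training"),
                      n_raters)
  assert_that(length(grades) == n_raters, "`grades` must have one per rater")
  assert_that(length(confidence_breaks) == 4L &&
                all(diff(confidence_breaks) > 0),
              "`confidence_breaks` must be 4 increasing cut points")
  structure(list(n_raters = as.integer(n_raters),
                 n_items = as.integer(n_items),
                 difficulty = difficulty, skill = skill, truth = truth,
                 grades = grades, confidence_breaks = confidence_breaks,
                 confidence_noise_sd = confidence_noise_sd,
                 seed = as.integer(seed)),
            class = "rater_model_params")
}

#' Simulate a rater-response table
#'
#' Draws every rater x polyp answer independently: correct with probability
#' `plogis(skill - difficulty)`, otherwise the opposite class; Likert
#' confidence is the (noisy) margin cut at `confidence_breaks`.
#'
#' @param params A [rater_model_params()] object.
#' @param seed Optional seed overriding `params$seed`.
#' @return `data.frame` with columns `rater_id`, `grade`, `polyp_id`,
#'   `answer`, `confidence`, `truth`, `correct` (long format, one row per
#'   rater x polyp cell).
#' @examples
#' tab <- simulate_rater_table(rater_model_params(n_raters = 4, n_items = 6,
#'                                                skill = 2))
#' mean(tab$correct)  # ~ plogis(2)
#' @export
simulate_rater_table <- function(params, seed = NULL) {
  assert_that(inherits(params, "rater_model_params"),
              "`params` must be a rater_model_params object")
  seed <- seed %||% params$seed
  nr <- params$n_raters; ni <- params$n_items
  margin <- outer(params$skill, params$difficulty, `-`)   # raters x items
  p_correct <- stats::plogis(margin)
  with_seed(seed, {
    correct <- matrix(stats::runif(nr * ni) < p_correct, nr, ni)
    truth_m <- matrix(params$truth, nr, ni, byrow = TRUE)
    other <- ifelse(truth_m == "cancer", "benign", "cancer")
    answer <- ifelse(correct, truth_m, other)
    conf_margin <- margin +
      matrix(stats::rnorm(nr * ni, 0, params$confidence_noise_sd), nr, ni)
    confidence <- matrix(
      findInterval(conf_margin, params$confidence_breaks) + 1L, nr, ni)
    data.frame(
      rater_id = rep(sprintf("R%02d", seq_len(nr)), times = ni),
      grade = rep(params$grades, times = ni),
      polyp_id = rep(seq_len(ni), each = nr),
      answer = as.vector(answer),
      confidence = as.vector(confidence),
      truth = as.vector(truth_m),
      correct = as.vector(correct),
      stringsAsFactors = FALSE)
  })
}
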