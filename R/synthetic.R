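#' Define a simulation design
#'
#' Describes a study to simulate: the generating item bank, the latent trait
#' distribution, completely-at-random missingness, an optional retest
#' occasion, grouped persons, and injected pathologies for pipeline power
#' studies.
#'
#' @param bank generating [item_bank()] (true parameters).
#' @param n_persons number of respondents at baseline.
#' @param theta_mean,theta_sd latent normal parameters (SD scale).
#' @param missing_rate proportion of cells masked, in \[0, 1).
#' @param group_probs optional named probabilities used to label persons
#'   (e.g. service user / carer mix); `NULL` for ungrouped data.
#' @param retest optional list `list(n_retest =, theta_correlation =)`.
#' @param pathologies list of pathology descriptors, each a list with
#'   `type` (one of `"disordered_thresholds"`, `"local_dependency"`,
#'   `"dif"`, `"low_scalability"`, `"nonmonotone"`), `item_ids`, and
#'   `magnitude`.  See [simulate_responses()] for their meanings.
#' @param seed integer RNG seed.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(bank, n_persons = 267, theta_mean = -0.08,
                              theta_sd = sqrt(1.90), missing_rate = 0.16,
                              group_probs = NULL, retest = NULL,
                              pathologies = list(), seed = 1) {
  stopifnot(inherits(bank, "item_bank"))
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (theta_sd <= 0) stop("theta_sd must be positive")
  for (p in pathologies) {
    if (!all(p$item_ids %in% bank$item_ids))
      stop("pathology names unknown item(s): ",
           paste(setdiff(p$item_ids, bank$item_ids), collapse = ", "))
    if (!p$type %in% c("disordered_thresholds", "local_dependency", "dif",
                       "low_scalability", "nonmonotone"))
      stop("unknown pathology type '", p$type, "'")
  }
  if (!is.null(retest)) {
    if (retest$n_retest > n_persons) stop("n_retest exceeds n_persons")
    if (retest$theta_correlation <= 0 || retest$theta_correlation > 1)
      stop("theta_correlation must be in (0, 1]")
  }
  structure(list(bank = bank, n_persons = n_persons, theta_mean = theta_mean,
                 theta_sd = theta_sd, missing_rate = missing_rate,
                 group_probs = group_probs, retest = retest,
                 pathologies = pathologies, seed = seed),
            class = "simulation_design")
}

#' A random generating bank of Likert items
#'
#' Thresholds are drawn uniformly on `delta_range` and sorted within item,
#' giving ordered 5-category (by default) partial-credit items.
#'
#' @param n_items number of items.
#' @param n_cats number of raw categories per item.
#' @param delta_range range thresholds are drawn from.
#' @param seed RNG seed.
#' @return An [item_bank()].
#' @export
random_bank <- function(n_items = 67, n_cats = 5, delta_range = c(-2.5, 2.5),
                        seed = 1) {
  set.seed(seed)
  deltas <- replicate(n_items,
                      sort(stats::runif(n_cats - 1, delta_range[1], delta_range[2])),
                      simplify = FALSE)
  item_bank(paste0("item", seq_len(n_items)), deltas)
}

#' The default study-emulation design
#'
#' Emulates the survey that produced the published bank: 67 five-category
#' Likert items, 267 respondents with latent trait N(-0.08, variance 1.90),
#' 16% completely-at-random missingness, a 67-person retest subsample with
#' latent correlation .75, a service-user/carer/both/unreported group mix of
#' 66/15/12/7%, and one injected pathology of each kind: disordered
#' thresholds (item3), a locally dependent triplet (items 10-12, copy
#' strength .7), one DIF item between service users and carers (item20,
#' threshold shift 1.6, sized to give a McFadden delta-R2 near the .06
#' observed in the development study), one unscalable item (item30, 80%
#' noise), and one unfolding non-monotone item (item40, full reflection).
#' Pathology magnitudes were calibrated by Monte-Carlo so each is
#' detectable by its pipeline stage at this sample size.
#'
#' @param seed RNG seed.
#' @return A [simulation_design()].
#' @export
study_design <- function(seed = 1) {
  bank <- random_bank(67, 5, seed = seed)
  simulation_design(
    bank, n_persons = 267, theta_mean = -0.08, theta_sd = sqrt(1.90),
    missing_rate = 0.16,
    group_probs = c(service_user = 0.66, carer = 0.15, both = 0.12,
                    unreported = 0.07),
    retest = list(n_retest = 67, theta_correlation = 0.75),
    pathologies = list(
      list(type = "disordered_thresholds", item_ids = "item3", magnitude = 1),
      list(type = "local_dependency", item_ids = c("item10", "item11"),
           magnitude = 0.7),
      list(type = "local_dependency", item_ids = c("item10", "item12"),
           magnitude = 0.7),
      list(type = "dif", item_ids = "item20", magnitude = 1.6),
      list(type = "low_scalability", item_ids = "item30", magnitude = 0.8),
      list(type = "nonmonotone", item_ids = "item40", magnitude = 1.0)),
    seed = seed)
}

## effective theta for the non-monotone pathology: an unfolding-style item
## whose operating curve turns downwards past its center.  magnitude is the
## fraction of slope reversed beyond the center (1 = full reflection, the
## response declines as fast as it rose; 0.5 = flat).
nonmonotone_theta <- function(theta, magnitude, center = 0) {
  ifelse(theta > center, theta - 2 * magnitude * (theta - center), theta)
}

#' Simulate responses from a design
#'
#' Each response is drawn from the partial credit category distribution at
#' the person's latent value; pathologies then perturb the named items;
#' missingness is applied completely at random.  Fully reproducible from the
#' design seed.
#'
#' @param design a [simulation_design()].
#' @return A [response_matrix()] with attributes `theta` (true latent
#'   values) and `design`.
#' @export
simulate_responses <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(design$seed)
  n <- design$n_persons
  bank <- design$bank
  theta <- stats::rnorm(n, design$theta_mean, design$theta_sd)
  group <- NULL
  if (!is.null(design$group_probs)) {
    group <- sample(names(design$group_probs), n, replace = TRUE,
                    prob = design$group_probs)
  }
  x <- generate_pcm_responses(bank, theta)
  for (p in design$pathologies) {
    idx <- match(p$item_ids, bank$item_ids)
    if (p$type == "disordered_thresholds") {
      # regenerate from reversed thresholds -> middle categories never modal
      for (j in idx) {
        b <- subset_bank(bank, j)
        b$deltas[[1]] <- rev(b$deltas[[1]])
        x[, j] <- generate_pcm_responses(b, theta)[, 1]
      }
    } else if (p$type == "nonmonotone") {
      for (j in idx)
        x[, j] <- generate_pcm_responses(subset_bank(bank, j),
                                         nonmonotone_theta(theta, p$magnitude))[, 1]
    } else if (p$type == "low_scalability") {
      # mixture with uniform noise kills the item-trait association
      for (j in idx) {
        noisy <- stats::runif(n) < p$magnitude
        m <- length(bank$deltas[[j]])
        x[noisy, j] <- sample(0:m, sum(noisy), replace = TRUE)
      }
    } else if (p$type == "dif") {
      if (is.null(group)) stop("dif pathology requires grouped persons")
      # shift thresholds for carers only, at equal theta
      carer <- group == "carer"
      for (j in idx) {
        b <- subset_bank(bank, j)
        b$deltas[[1]] <- b$deltas[[1]] + p$magnitude
        x[carer, j] <- generate_pcm_responses(b, theta[carer])[, 1]
      }
    }
    # local_dependency handled after all marginal draws, below
  }
  for (p in design$pathologies) {
    if (p$type != "local_dependency") next
    x <- ld_copy(x, match(p$item_ids[1], bank$item_ids),
                 match(p$item_ids[2], bank$item_ids), p$magnitude)
  }
  if (design$missing_rate > 0) {
    mask <- matrix(stats::runif(n * ncol(x)) < design$missing_rate, n, ncol(x))
    x[mask] <- NA_integer_
  }
  out <- response_matrix(x, item_ids = bank$item_ids, group = group,
                         max_cat = vapply(bank$deltas, length, 1L))
  attr(out, "theta") <- theta
  attr(out, "design") <- design
  out
}

ld_copy <- function(x, i, j, strength) {
  pick <- stats::runif(nrow(x)) < strength
  x[pick, j] <- x[pick, i]
  x
}

#' Inject local dependency into an existing matrix
#'
#' The second item of the pair is regenerated as a mixture: with probability
#' `strength` it copies the first item's response, otherwise it keeps its
#' original model draw.
#'
#' @param matrix a [response_matrix()].
#' @param item_pair character vector of two item ids.
#' @param strength copy probability in (0, 1\].
#' @param seed RNG seed.
#' @return The modified [response_matrix()].
#' @export
inject_local_dependency <- function(matrix, item_pair, strength, seed = 1) {
  stopifnot(inherits(matrix, "response_matrix"), length(item_pair) == 2)
  idx <- match(item_pair, matrix$item_ids)
  if (anyNA(idx)) stop("item(s) not found: ",
                       paste(item_pair[is.na(idx)], collapse = ", "))
  if (strength < 0 || strength > 1) stop("strength must be in [0, 1]")
  if (strength == 0) return(matrix)
  set.seed(seed)
  matrix$responses <- ld_copy(matrix$responses, idx[1], idx[2], strength)
  matrix
}

#' Add a differential-functioning item to a design
#'
#' Registers a `dif` pathology: the named item's generating thresholds are
#' shifted by `group_shift` for the carer group only, so the two groups
#' differ in their response probabilities at equal theta.
#'
#' @param design a [simulation_design()] with `group_probs` set.
#' @param item_id the affected item.
#' @param group_shift threshold offset applied to one group.
#' @return The amended design.
#' @export
inject_dif <- function(design, item_id, group_shift) {
  stopifnot(inherits(design, "simulation_design"))
  if (is.null(design$group_probs)) stop("design has no group labels")
  if (!item_id %in% design$bank$item_ids) stop("item not found: ", item_id)
  design$pathologies <- c(design$pathologies,
                          list(list(type = "dif", item_ids = item_id,
                                    magnitude = group_shift)))
  design
}

#' Simulate the retest occasion
#'
#' Retest latent values follow
#' `theta2 = mu + rho (theta1 - mu) + sqrt(1 - rho^2) sd z`, preserving the
#' marginal distribution; responses are fresh PCM draws.  Person ids are the
#' baseline ids of the retest subsample so occasions can be paired.
#'
#' @param design a [simulation_design()] with a `retest` block.
#' @param baseline the baseline [response_matrix()] from
#'   [simulate_responses()] (supplies true thetas and ids).
#' @return A [response_matrix()] for the retest subsample with attribute
#'   `theta`.
#' @export
simulate_retest <- function(design, baseline) {
  stopifnot(inherits(design, "simulation_design"),
            inherits(baseline, "response_matrix"))
  if (is.null(design$retest)) stop("design has no retest block")
  theta1 <- attr(baseline, "theta")
  if (is.null(theta1)) stop("baseline carries no true thetas")
  set.seed(design$seed + 1L)
  nr <- design$retest$n_retest
  rho <- design$retest$theta_correlation
  pick <- sort(sample(design$n_persons, nr))
  mu <- design$theta_mean; sd <- design$theta_sd
  theta2 <- mu + rho * (theta1[pick] - mu) +
    sqrt(1 - rho^2) * sd * stats::rnorm(nr)
  x <- generate_pcm_responses(design$bank, theta2)
  if (design$missing_rate > 0) {
    mask <- matrix(stats::runif(nr * ncol(x)) < design$missing_rate, nr, ncol(x))
    x[mask] <- NA_integer_
  }
  out <- response_matrix(x, person_ids = baseline$person_ids[pick],
                         item_ids = design$bank$item_ids,
                         group = if (is.null(baseline$group)) NULL else
                           baseline$group[pick],
                         max_cat = vapply(design$bank$deltas, length, 1L))
  attr(out, "theta") <- theta2
  out
}
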