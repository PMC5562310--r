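# Bundled group profiles and log-normal moment matching.

#' Plasma miRNA group profiles bundled with the package
#'
#' Returns the published per-group summary profiles (mean and standard
#' deviation of the normalized plasma abundance, on the 2^-dCt scale) of 16
#' circulating miRNAs — 14 cellular and 2 herpesvirus-encoded — measured by
#' qRT-PCR in four patient cohorts: sepsis (n = 99), healthy controls
#' (n = 53), pre-surgery (n = 19) and post-surgery (n = 11).  These profiles
#' parameterize the synthetic-data generator; per-patient data were never
#' deposited, so the marginal moments are all the generator can be anchored
#' to.
#'
#' @param group optional group label; one of `"sepsis"`, `"control"`,
#'   `"pre_surgery"`, `"post_surgery"`.  If omitted, profiles for all four
#'   groups are returned as a named list.
#' @return A `group_profile` data frame with columns `mirna`, `mean`, `sd`
#'   and a `group` attribute (or a named list of them).
#' @examples
#' prof <- group_profiles("sepsis")
#' prof[prof$mirna == "miR-16", ]
#' @export
group_profiles <- function(group = NULL) {
  path <- system.file("extdata", "plasma_mirna_profiles.tsv",
                      package = "spongenet", mustWork = TRUE)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  groups <- unique(tab$group)
  make_one <- function(g) {
    prof <- tab[tab$group == g, c("mirna", "mean", "sd")]
    rownames(prof) <- NULL
    attr(prof, "group") <- g
    class(prof) <- c("group_profile", "data.frame")
    validate_group_profile(prof)
  }
  if (is.null(group)) {
    profs <- lapply(groups, make_one)
    names(profs) <- groups
    return(profs)
  }
  group <- match.arg(group, groups)
  make_one(group)
}

#' Construct a group profile from miRNA means and standard deviations
#'
#' @param mirna character vector of unique miRNA ids.
#' @param mean,sd strictly positive numeric vectors on the 2^-dCt scale.
#' @param group label attached to the profile.
#' @return A `group_profile` data frame.
#' @export
group_profile <- function(mirna, mean, sd, group = "custom") {
  prof <- data.frame(mirna = as.character(mirna), mean = mean, sd = sd,
                     stringsAsFactors = FALSE)
  attr(prof, "group") <- group
  class(prof) <- c("group_profile", "data.frame")
  validate_group_profile(prof)
}

validate_group_profile <- function(prof) {
  if (anyDuplicated(prof$mirna)) abort("miRNA ids in a profile must be unique")
  if (any(prof$mean <= 0) || any(prof$sd <= 0)) {
    abort("profile means and sds must be strictly positive")
  }
  invisible(prof)
}

#' Cohort sizes of the four patient groups
#'
#' @return Named integer vector of sample sizes used when a generator call
#'   does not override `n_samples`.
#' @export
group_sizes <- function() {
  c(sepsis = 99L, control = 53L, pre_surgery = 19L, post_surgery = 11L)
}

#' The sponged (S) and connected (C) miRNA groups
#'
#' The differential correlation network partitions the measured miRNAs into
#' a C group (pairwise connected in both control and sepsis) and an S group
#' (well connected in control, fully isolated in sepsis, interpreted as
#' sponged).  These memberships also parameterize the study-emulating
#' latent correlation structure.
#'
#' @return Named list with elements `S` and `C` of miRNA ids.
#' @export
mirna_groups <- function() {
  list(
    S = c("miR-182", "miR-146", "miR-155", "miR-16", "miR-29a"),
    C = c("miR-23", "miR-26a", "miR-26b", "miR-93", "miR-223", "miR-21")
  )
}

#' Log-normal parameters from a target mean and standard deviation
#'
#' Moment matching: a log-normal with parameters `(mu, sigma)` has mean
#' `exp(mu + sigma^2/2)` and variance `(exp(sigma^2) - 1) exp(2 mu + sigma^2)`.
#' Inverting gives `sigma^2 = log(1 + sd^2/mean^2)` and
#' `mu = log(mean) - sigma^2/2`.  The log-normal family is used because the
#' bundled profiles have SD far above the mean on a positive scale (e.g.
#' miR-150 in sepsis, 0.141 +/- 0.669), which no normal marginal can honour.
#'
#' @param mean,sd strictly positive target moments (vectorized).
#' @return List with numeric components `mu` and `sigma`.
#' @examples
#' p <- lognormal_params(11.5914, 28.3203)
#' exp(p$mu + p$sigma^2 / 2) # recovers the mean
#' @export
lognormal_params <- function(mean, sd) {
  if (any(!is.finite(mean)) || any(!is.finite(sd)) ||
      any(mean <= 0) || any(sd <= 0)) {
    abort("lognormal_params() requires strictly positive finite mean and sd")
  }
  sigma2 <- log(1 + sd^2 / mean^2)
  list(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}
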