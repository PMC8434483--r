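# Synthetic fixtures: descriptor matrices with planted linear structure and
# a toy molecule set covering every curation rule.

#' Specification for a synthetic descriptor matrix
#'
#' Descriptor columns are standard-normal with pairwise equicorrelation
#' `inter_descriptor_correlation`; the response is a linear combination of
#' `support_size` planted columns plus Gaussian noise. When `target_r2` is
#' given, `noise_sd` is derived analytically from the population signal
#' variance b' S b (S the equicorrelation matrix) so that the population R2
#' equals the target.
#'
#' @param n_molecules Number of rows.
#' @param n_descriptors Number of descriptor columns.
#' @param support_size Number of planted active descriptors.
#' @param coefficients Coefficients of the planted support (recycled /
#'   truncated to `support_size`). Default alternates signs with decreasing
#'   magnitude.
#' @param intercept Intercept of the planted model.
#' @param noise_sd Gaussian noise standard deviation (ignored when
#'   `target_r2` is given).
#' @param target_r2 Optional population R2 in (0, 1) from which `noise_sd`
#'   is derived.
#' @param inter_descriptor_correlation Equicorrelation in `[0, 1)` between
#'   descriptor columns.
#' @param n_near_duplicates Number of extra columns appended as noisy copies
#'   of support columns (pairwise r > 0.9) to exercise correlation pruning
#'   and swap refinement.
#' @param add_screen_traps Append a ~96%-zeros column and a two-valued
#'   column to exercise descriptor screening rules.
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_molecules = 160L, n_descriptors = 60L,
                           support_size = 5L,
                           coefficients = NULL, intercept = 6,
                           noise_sd = 1, target_r2 = NULL,
                           inter_descriptor_correlation = 0.2,
                           n_near_duplicates = 0L,
                           add_screen_traps = FALSE,
                           seed = 1L) {
  if (support_size > n_descriptors) stop_gg("support_size must be <= n_descriptors")
  if (inter_descriptor_correlation < 0 || inter_descriptor_correlation >= 1) {
    stop_gg("inter_descriptor_correlation must be in [0, 1)")
  }
  if (noise_sd < 0) stop_gg("noise_sd must be >= 0")
  if (is.null(coefficients)) {
    coefficients <- c(2, -1.5, 1, 1, -0.5, rep(c(1, -1), length.out = max(0, support_size - 5)))
  }
  coefficients <- rep_len(coefficients, support_size)
  if (!is.null(target_r2)) {
    if (target_r2 <= 0 || target_r2 >= 1) stop_gg("target_r2 must be in (0, 1)")
    sig <- signal_variance(coefficients, inter_descriptor_correlation)
    noise_sd <- sqrt(sig * (1 - target_r2) / target_r2)
  }
  structure(list(
    n_molecules = as.integer(n_molecules),
    n_descriptors = as.integer(n_descriptors),
    support_size = as.integer(support_size),
    coefficients = coefficients, intercept = intercept,
    noise_sd = noise_sd,
    inter_descriptor_correlation = inter_descriptor_correlation,
    n_near_duplicates = as.integer(n_near_duplicates),
    add_screen_traps = isTRUE(add_screen_traps),
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# population signal variance b' S b under unit-variance equicorrelated columns
signal_variance <- function(b, rho) {
  sum(b^2) + rho * (sum(b)^2 - sum(b^2))
}

#' Generate a synthetic descriptor matrix with a planted linear response
#'
#' @param spec A [synthetic_spec()].
#' @return List with `matrix` (a `descriptor_matrix`), `y` (named pKi-like
#'   response), `true_support` (planted descriptor names), `model` (the
#'   planted intercept/coefficients), and `population_r2` (analytic
#'   signal/(signal+noise) ratio).
#' @examples
#' fx <- generate_matrix(synthetic_spec(n_molecules = 50, n_descriptors = 10,
#'                                      support_size = 2, seed = 7))
#' fit_mlr(fx$matrix, fx$y, names = fx$true_support)
#' @export
generate_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_molecules
  p <- spec$n_descriptors
  rho <- spec$inter_descriptor_correlation
  with_seed(spec$seed, {
    common <- stats::rnorm(n)
    X <- sqrt(rho) * common + sqrt(1 - rho) * matrix(stats::rnorm(n * p), n, p)
    desc_names <- sprintf("D%03d", seq_len(p))
    support <- sort(sample(desc_names, spec$support_size))
    colnames(X) <- desc_names
    y <- spec$intercept +
      drop(X[, support, drop = FALSE] %*% spec$coefficients) +
      stats::rnorm(n, sd = spec$noise_sd)

    if (spec$n_near_duplicates > 0) {
      src <- rep_len(support, spec$n_near_duplicates)
      dup <- vapply(src, function(s) {
        X[, s] + stats::rnorm(n, sd = 0.15)  # r ~ 0.99 with the source column
      }, numeric(n))
      colnames(dup) <- sprintf("%s_dup%d", src, seq_len(spec$n_near_duplicates))
      X <- cbind(X, dup)
    }
    if (spec$add_screen_traps) {
      zero_dom <- numeric(n)
      nz <- max(1L, floor(0.04 * n))
      zero_dom[sample(n, nz)] <- stats::runif(nz, 1, 2)
      two_valued <- sample(c(0, 5.6826), n, replace = TRUE)
      X <- cbind(X, mostly_zero = zero_dom, two_valued = two_valued)
    }
    ids <- sprintf("mol%04d", seq_len(n))
    rownames(X) <- ids
    names(y) <- ids

    sig <- signal_variance(spec$coefficients, rho)
    list(
      matrix = descriptor_matrix(X, provider = "synthetic"),
      y = y,
      true_support = support,
      model = list(intercept = spec$intercept,
                   coefficients = stats::setNames(spec$coefficients, support)),
      population_r2 = sig / (sig + spec$noise_sd^2)
    )
  })
}

#' Toy molecule set spanning every curation rule
#'
#' Around twenty hand-written SMILES with activities, designed so that the
#' default curation criteria reject at least one molecule for each reason:
#' molecular weight over 500, Ki over 5000 nM, no basic ring nitrogen,
#' unspecified stereocentre, the bridged 9-azabicyclo[3.3.1]nonane scaffold,
#' and an unparsable entry.
#'
#' @return data.frame with columns `id`, `smiles`, `ki_nM`, `source_ref` and
#'   `expect_reject` (the designed rejection reason, `""` for keepers) for
#'   use in examples and tests.
#' @export
toy_molecule_set <- function() {
  rec <- function(id, smiles, ki, reason = "") {
    data.frame(id = id, smiles = smiles, ki_nM = ki,
               source_ref = "toy", expect_reject = reason,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    # keepers: basic ring N (piperidine / piperazine / pyrrolidine cores)
    rec("keep_piperidine",  "CCN1CCCCC1", 120),
    rec("keep_piperazine",  "c1ccccc1N1CCN(C)CC1", 45),
    rec("keep_pyrrolidine", "C1CCN(CCc2ccccc2)C1", 800),
    rec("keep_morpholine",  "O1CCN(Cc2ccccc2)CC1", 2500),
    rec("keep_benzylpiperidine", "C1CN(CCCc2ccc(F)cc2)CCC1", 60),
    rec("keep_stereo_ok",   "C[C@H](c1ccccc1)N1CCCCC1", 300),
    rec("keep_tetrahydroisoquinoline", "C1Cc2ccccc2CN1CCC(=O)c1ccccc1", 95),
    rec("keep_chloro",      "Clc1ccc(CN2CCNCC2)cc1", 700),
    rec("keep_high_but_ok_ki", "CCCN1CCCCC1", 4999),
    rec("keep_small_amine", "CN1CCCC1", 1500),
    # designed rejections
    rec("rej_mw",           "N1(CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC)CCCCC1", 50, "mw"),
    rec("rej_ki",           "CN1CCN(CC1)c1ccccc1F", 5200, "ki"),
    rec("rej_pyridine",     "c1ccncc1CC", 900, "no_basic_ring_N"),
    rec("rej_no_N",         "CCOc1ccccc1", 1000, "no_basic_ring_N"),
    rec("rej_amide_only",   "O=C(N1CCCCC1)c1ccccc1", 1200, "no_basic_ring_N"),
    rec("rej_stereo",       "CC(c1ccccc1)N1CCCCC1", 150, "unspecified_stereo"),
    rec("rej_granatanine",  "CN1C2CCCC1CCC2", 80, "excluded_scaffold"),
    rec("rej_parse",        "C1CC(", 10, "parse_error"),
    # extra chemistry variety for descriptor tests
    rec("keep_acceptor_rich", "COc1ccc(CCN2CCOCC2)cc1OC", 2100),
    rec("keep_nitrile",     "N#CCCN1CCCCC1", 3000)
  ))
}
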