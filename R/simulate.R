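#' Configuration for the synthetic summary-statistics generator
#'
#' Defines the structural model behind [simulate_triple()] and
#' [simulate_panel()]: a continuous exposure, a continuous mediator and a
#' binary (log-odds scale) outcome, measured in three non-overlapping GWAS
#' samples over a common set of independent SNPs.
#'
#' A fraction `prop_causal` of SNPs carry true exposure effects
#' `gamma_j ~ N(0, gamma_sd^2)`; a disjoint fraction `prop_causal_mediator`
#' carry mediator-specific effects `delta_j ~ N(0, gamma_sd^2)` so the
#' mediator has instruments of its own (without them, every mediator
#' instrument would act through the exposure and the mediator -> outcome
#' leg would be unidentifiable in the presence of a direct effect). True
#' effects propagate along the causal graph:
#' mediator `= theta_xm * gamma + delta`, outcome
#' `= (theta_xm*theta_my + theta_xy_direct) * gamma + theta_my * delta +
#' alpha`, where `alpha_j ~ N(pleiotropy_mean, pleiotropy_sd^2)` on a
#' `pleiotropy_frac` fraction of the exposure-causal SNPs (direct,
#' exclusion-restriction-violating paths).
#'
#' Estimated effects add sampling noise with the standardized-trait
#' standard error `se = (2 p (1-p) n)^(-1/2)` at minor allele frequency p;
#' the binary outcome's se is inflated by `(phi(1-phi))^(-1/2)` at case
#' fraction `phi = 0.5`. Default sample sizes mirror the immune-trait
#' (3,757) and metabolite (8,299) GWASs; the outcome defaults to 10,000.
#' SNPs are placed across 22 chromosomes at greater than clump-window
#' spacing, so distance clumping is a no-op by construction.
#'
#' @param n_snp number of SNPs (default 200).
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes (each >= 100).
#' @param prop_causal fraction of SNPs with nonzero exposure effect
#'   (default 0.25).
#' @param prop_causal_mediator fraction with mediator-specific effects
#'   (default equal to `prop_causal`; the two sets are disjoint).
#' @param gamma_sd SD of true effect sizes (default 0.15 SD units per
#'   allele).
#' @param theta_xm exposure -> mediator causal effect (default 0.4).
#' @param theta_my mediator -> outcome causal effect, log-odds (default 0.3).
#' @param theta_xy_direct direct exposure -> outcome effect, log-odds
#'   (default 0.1).
#' @param pleiotropy_frac fraction of exposure-causal SNPs with direct
#'   outcome effects (default 0).
#' @param pleiotropy_mean,pleiotropy_sd distribution of those direct
#'   effects.
#' @param maf_range minor-allele-frequency range, in (0, 0.5]
#'   (default c(0.05, 0.5)).
#' @param seed integer seed (mandatory).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_snp = 200L,
                              n_exposure = 3757L, n_mediator = 8299L,
                              n_outcome = 10000L,
                              prop_causal = 0.25,
                              prop_causal_mediator = prop_causal,
                              gamma_sd = 0.15,
                              theta_xm = 0.4, theta_my = 0.3,
                              theta_xy_direct = 0.1,
                              pleiotropy_frac = 0,
                              pleiotropy_mean = 0, pleiotropy_sd = 0.02,
                              maf_range = c(0.05, 0.5),
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  problems <- character()
  chk <- function(cond, msg) if (!cond) problems <<- c(problems, msg)
  chk(n_snp >= 1, "n_snp must be >= 1")
  chk(all(c(n_exposure, n_mediator, n_outcome) >= 100), "sample sizes must be >= 100")
  chk(prop_causal >= 0 && prop_causal <= 1, "prop_causal must be in [0,1]")
  chk(prop_causal_mediator >= 0 && prop_causal_mediator <= 1,
      "prop_causal_mediator must be in [0,1]")
  chk(prop_causal + prop_causal_mediator <= 1,
      "prop_causal + prop_causal_mediator must be <= 1 (disjoint causal sets)")
  chk(pleiotropy_frac >= 0 && pleiotropy_frac <= 1, "pleiotropy_frac must be in [0,1]")
  chk(gamma_sd >= 0, "gamma_sd must be >= 0")
  chk(length(maf_range) == 2 && maf_range[1] > 0 && maf_range[2] <= 0.5 &&
        maf_range[1] <= maf_range[2], "maf_range must lie in (0, 0.5]")
  if (length(problems) > 0L) stop("invalid simulation config: ",
                                  paste(problems, collapse = "; "))
  structure(list(n_snp = as.integer(n_snp), n_exposure = as.integer(n_exposure),
                 n_mediator = as.integer(n_mediator), n_outcome = as.integer(n_outcome),
                 prop_causal = prop_causal,
                 prop_causal_mediator = prop_causal_mediator,
                 gamma_sd = gamma_sd, theta_xm = theta_xm, theta_my = theta_my,
                 theta_xy_direct = theta_xy_direct,
                 pleiotropy_frac = pleiotropy_frac,
                 pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
                 maf_range = maf_range, seed = as.integer(seed)),
            class = "simulation_config")
}

# non-palindromic allele pairs only, so harmonization never drops
# synthetic variants as strand-ambiguous
.allele_pairs <- rbind(c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
                       c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T"))

.snp_map <- function(n_snp, spacing_bp = 10001000) {
  chrom <- as.character(rep_len(1:22, n_snp))
  idx <- stats::ave(seq_len(n_snp), chrom, FUN = seq_along)
  data.frame(SNP = sprintf("rs%06d", seq_len(n_snp)), CHR = chrom,
             BP = (idx - 1) * spacing_bp + 1, stringsAsFactors = FALSE)
}

.make_trait <- function(map, eaf, true_beta, n, trait_id, trait_type,
                        binary = FALSE, pair_idx) {
  se <- 1 / sqrt(2 * eaf * (1 - eaf) * n)
  if (binary) se <- se / sqrt(0.5 * 0.5)  # x (phi(1-phi))^(-1/2) at phi = 0.5
  beta_hat <- stats::rnorm(length(true_beta), true_beta, se)
  df <- data.frame(SNP = map$SNP, CHR = map$CHR, BP = map$BP,
                   EA = .allele_pairs[pair_idx, 1],
                   OA = .allele_pairs[pair_idx, 2],
                   EAF = eaf, BETA = beta_hat, SE = se,
                   P = pmax(2 * stats::pnorm(-abs(beta_hat / se)),
                            .Machine$double.xmin),
                   N = n, stringsAsFactors = FALSE)
  gwas_sumstats(df, trait_id = trait_id, trait_type = trait_type, quiet = TRUE)
}

#' Simulate an exposure-mediator-outcome summary-statistics triple
#'
#' Draws one realisation of the structural model described in
#' [simulation_config()] and returns the three GWAS summary-statistic
#' tables together with the ground truth. The three traits receive
#' independent noise draws (non-overlapping samples). Identical seeds give
#' bit-identical output.
#'
#' @param cfg a [simulation_config()].
#' @return List with `exposure`, `mediator`, `outcome` (each a
#'   [gwas_sumstats()]) and `truth`, a list holding the per-SNP true effects
#'   (`snp_effects` data.frame), the structural coefficients, and the
#'   implied `total`, `mediated`, `direct` effects and mediation
#'   `proportion_pct`.
#' @export
simulate_triple <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  withr::with_seed(cfg$seed, .simulate_triple_impl(cfg))
}

.simulate_triple_impl <- function(cfg) {
  n <- cfg$n_snp
  map <- .snp_map(n)
  eaf <- stats::runif(n, cfg$maf_range[1], cfg$maf_range[2])
  pair_idx <- sample.int(nrow(.allele_pairs), n, replace = TRUE)

  n_cx <- round(cfg$prop_causal * n)
  n_cm <- round(cfg$prop_causal_mediator * n)
  role <- rep("null", n)
  role[seq_len(n_cx)] <- "exposure"
  if (n_cm > 0) role[n_cx + seq_len(n_cm)] <- "mediator"

  gamma <- ifelse(role == "exposure", stats::rnorm(n, 0, cfg$gamma_sd), 0)
  delta <- ifelse(role == "mediator", stats::rnorm(n, 0, cfg$gamma_sd), 0)
  alpha <- rep(0, n)
  if (cfg$pleiotropy_frac > 0 && n_cx > 0) {
    pleio <- which(role == "exposure" &
                     stats::runif(n) < cfg$pleiotropy_frac)
    alpha[pleio] <- stats::rnorm(length(pleio), cfg$pleiotropy_mean,
                                 cfg$pleiotropy_sd)
  }

  total_coef <- cfg$theta_xm * cfg$theta_my + cfg$theta_xy_direct
  bx_true <- gamma
  bm_true <- cfg$theta_xm * gamma + delta
  # pleiotropic shifts are directional with respect to the
  # exposure-increasing allele (otherwise allele-orientation symmetry makes
  # their mean unidentifiable by design)
  by_true <- total_coef * gamma + cfg$theta_my * delta + sign(gamma) * alpha

  exposure <- .make_trait(map, eaf, bx_true, cfg$n_exposure, "exposure",
                          "continuous", binary = FALSE, pair_idx)
  mediator <- .make_trait(map, eaf, bm_true, cfg$n_mediator, "mediator",
                          "continuous", binary = FALSE, pair_idx)
  outcome <- .make_trait(map, eaf, by_true, cfg$n_outcome, "outcome",
                         "binary", binary = TRUE, pair_idx)

  mediated <- cfg$theta_xm * cfg$theta_my
  truth <- list(
    snp_effects = data.frame(SNP = map$SNP, role = role, gamma = gamma,
                             delta = delta, alpha = alpha,
                             beta_exposure = bx_true, beta_mediator = bm_true,
                             beta_outcome = by_true, stringsAsFactors = FALSE),
    theta_xm = cfg$theta_xm, theta_my = cfg$theta_my,
    theta_xy_direct = cfg$theta_xy_direct,
    total = total_coef, mediated = mediated,
    direct = cfg$theta_xy_direct,
    proportion_pct = if (total_coef != 0) 100 * mediated / total_coef else NA_real_
  )
  list(exposure = exposure, mediator = mediator, outcome = outcome, truth = truth)
}

#' Simulate a multi-trait exposure panel sharing one outcome
#'
#' Emulates a screening study: `n_traits` exposure-like traits, each with
#' its own block of independent SNPs, of which `n_causal_traits` have a
#' true causal effect `theta` on a shared binary outcome. Used to exercise
#' the screen + FDR machinery end-to-end with known positives.
#'
#' @param cfg a [simulation_config()]; `n_snp` is the per-trait block size
#'   and the theta/mediator fields are ignored.
#' @param n_traits number of exposure traits.
#' @param n_causal_traits number with a nonzero causal effect (the first
#'   `n_causal_traits` trait ids).
#' @param theta causal effect of each causal trait on the outcome
#'   (default 0.3, log-odds per SD).
#' @return List with `exposures` (named list of [gwas_sumstats()]),
#'   `outcome` (a single [gwas_sumstats()] spanning all blocks), and
#'   `causal` (named logical vector of truth labels).
#' @export
simulate_panel <- function(cfg, n_traits, n_causal_traits, theta = 0.3) {
  stopifnot(inherits(cfg, "simulation_config"), n_causal_traits <= n_traits)
  withr::with_seed(cfg$seed, {
    per <- cfg$n_snp
    map <- .snp_map(per * n_traits)
    eaf <- stats::runif(per * n_traits, cfg$maf_range[1], cfg$maf_range[2])
    pair_idx <- sample.int(nrow(.allele_pairs), per * n_traits, replace = TRUE)
    causal <- stats::setNames(seq_len(n_traits) <= n_causal_traits,
                              sprintf("trait_%02d", seq_len(n_traits)))
    by_true <- numeric(per * n_traits)
    exposures <- vector("list", n_traits)
    for (t in seq_len(n_traits)) {
      block <- (t - 1) * per + seq_len(per)
      n_cx <- round(cfg$prop_causal * per)
      gamma <- c(stats::rnorm(n_cx, 0, cfg$gamma_sd), rep(0, per - n_cx))
      by_true[block] <- if (causal[t]) theta * gamma else 0
      exposures[[t]] <- .make_trait(map[block, ], eaf[block], gamma,
                                    cfg$n_exposure, names(causal)[t],
                                    "continuous", binary = FALSE,
                                    pair_idx[block])
    }
    names(exposures) <- names(causal)
    outcome <- .make_trait(map, eaf, by_true, cfg$n_outcome, "outcome",
                           "binary", binary = TRUE, pair_idx)
    list(exposures = exposures, outcome = outcome, causal = causal)
  })
}

#' Write a simulated triple to disk
#'
#' Writes the three summary-statistic tables as canonical TSVs plus the
#' ground truth as JSON (scalar truth fields only; per-SNP effects go in a
#' fourth TSV).
#'
#' @param sim result of [simulate_triple()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_simulated_triple <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("exposure.tsv", "mediator.tsv", "outcome.tsv",
                            "truth_snp_effects.tsv", "truth.json"))
  write_sumstats(sim$exposure, paths[1])
  write_sumstats(sim$mediator, paths[2])
  write_sumstats(sim$outcome, paths[3])
  utils::write.table(sim$truth$snp_effects, paths[4], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  scalars <- sim$truth[setdiff(names(sim$truth), "snp_effects")]
  writeLines(paste0("{", paste(sprintf('"%s": %.15g', names(scalars),
                                       unlist(scalars)), collapse = ", "), "}"),
             paths[5])
  invisible(paths)
}
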