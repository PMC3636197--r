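# ---- seeded synthetic-data generators ----
#
# Every generator is a pure function of its config: randomness is drawn
# inside withr::with_seed() on an offset of config$seed, so repeated calls
# with the same config give identical output and generators do not disturb
# the caller's RNG state.

#' Published descriptor statistics of the natural-product library
#'
#' Mean and standard deviation of the eight chemical-space descriptors as
#' reported for the UNPD natural-product collection, together with the
#' sampling family used to emulate each marginal: `normal` (AlogP, which
#' spans negative values), `lognormal` (molecular weight, positive and
#' right-skewed), `nbinom` (counts with variance above the mean; a Poisson
#' is substituted automatically when the printed variance is at or below
#' the mean) and `beta` (the fractional polar surface area, bounded in
#' `[0, 1]`). All families are moment-matched so the distribution mean
#' equals the printed mean exactly.
#'
#' @format data frame: `descriptor`, `mean`, `sd`, `family`.
#' @export
np_descriptor_params <- data.frame(
  descriptor = DESCRIPTOR_COLS,
  mean = c(2.788, 472.6, 6.6, 3.7, 0.9, 7.5, 3.4, 0.248),
  sd = c(3.352, 265.7, 6.8, 2.4, 1.3, 6.7, 4.1, 0.128),
  family = c("normal", "lognormal", "nbinom", "nbinom", "nbinom", "nbinom",
             "nbinom", "beta"),
  stringsAsFactors = FALSE
)

#' Published descriptor statistics of approved small-molecule drugs
#'
#' Same layout as [np_descriptor_params], with the means and standard
#' deviations reported for FDA-approved small-molecule drugs.
#'
#' @format data frame: `descriptor`, `mean`, `sd`, `family`.
#' @export
drug_descriptor_params <- data.frame(
  descriptor = DESCRIPTOR_COLS,
  mean = c(1.899, 360.8, 5.5, 2.7, 1.3, 5.2, 2.3, 0.277),
  sd = c(2.814, 199.1, 4.9, 1.6, 1.1, 4.2, 2.6, 0.171),
  family = c("normal", "lognormal", "nbinom", "nbinom", "nbinom", "nbinom",
             "nbinom", "beta"),
  stringsAsFactors = FALSE
)

#' Configuration for the synthetic-data generators
#'
#' Defaults reproduce the study conditions the analysis assumes: a
#' docking-campaign-sized library (2884 compounds x 243 targets, the size
#' of the docking-based drug-target network), descriptor marginals at the
#' published natural-product means/SDs, a scale-free compound-degree
#' distribution with exponent 1.125, a docking-score background centered
#' well below the admissibility cutoffs, and strong binders planted in the
#' 9-11 score range.
#'
#' @param seed integer seed; all generators derive their randomness from it.
#' @param n_compounds,n_targets,n_diseases entity counts (all >= 1).
#' @param descriptor_params data frame as [np_descriptor_params] (the
#'   default) or [drug_descriptor_params].
#' @param degree_exponent magnitude of the power-law exponent for compound
#'   degrees (default 1.125).
#' @param degree_max truncation of the compound degree distribution
#'   (default 8, which puts the mean at about 2.7 targets per compound,
#'   the multi-target breadth reported for natural-product drug-target
#'   networks; must not exceed `n_targets`).
#' @param target_weight_exponent Zipf exponent for preferential target
#'   attachment (default 1; heavier targets collect more compounds,
#'   emulating promiscuous binding sites).
#' @param interaction_score_mean,interaction_score_sd experimental affinity
#'   scale (pKd-like) for [gen_interaction_network()].
#' @param background_mean,background_sd docking-score background (default
#'   mean 5, sd 1.5, truncated at 0).
#' @param pairs_per_compound scored background pairs per compound in the
#'   docking table (default 5, a sparse per-compound score report).
#' @param planted_binder_fraction fraction of compounds given one planted
#'   strong binder (default 0.1; must be in `[0, 1]`).
#' @param planted_range score range of planted binders (default 9-11,
#'   above the stringent cutoff).
#' @param reference_mean,reference_sd,reference_cap reference-ligand score
#'   distribution (normal, truncated to `(0, reference_cap]`; the cap of
#'   8.8 keeps reference ligands below the planted range so planted
#'   binders are admissible by construction).
#' @param disease_targets_range range of target-set sizes per disease.
#' @return validated list of class `np_config`.
#' @export
generator_config <- function(seed,
                             n_compounds = 2884,
                             n_targets = 243,
                             n_diseases = 30,
                             descriptor_params = np_descriptor_params,
                             degree_exponent = 1.125,
                             degree_max = 8,
                             target_weight_exponent = 1,
                             interaction_score_mean = 6.5,
                             interaction_score_sd = 1.2,
                             background_mean = 5,
                             background_sd = 1.5,
                             pairs_per_compound = 5,
                             planted_binder_fraction = 0.1,
                             planted_range = c(9, 11),
                             reference_mean = 7,
                             reference_sd = 1,
                             reference_cap = 8.8,
                             disease_targets_range = c(1, 8)) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (n_compounds < 1 || n_targets < 1 || n_diseases < 1) {
    stop("entity counts must be >= 1", call. = FALSE)
  }
  stopifnot(is.data.frame(descriptor_params),
            all(c("descriptor", "mean", "sd", "family") %in%
                  names(descriptor_params)))
  if (any(descriptor_params$sd < 0)) stop("descriptor sd must be >= 0",
                                          call. = FALSE)
  if (degree_max > n_targets) {
    stop("degree_max cannot exceed n_targets", call. = FALSE)
  }
  if (planted_binder_fraction < 0 || planted_binder_fraction > 1) {
    stop("planted_binder_fraction must be in [0, 1]", call. = FALSE)
  }
  if (planted_range[1] >= planted_range[2]) {
    stop("planted_range must be increasing", call. = FALSE)
  }
  if (reference_cap >= planted_range[1]) {
    stop("reference_cap must stay below the planted score range",
         call. = FALSE)
  }
  if (background_sd <= 0 || reference_sd <= 0) {
    stop("score sds must be > 0", call. = FALSE)
  }
  if (pairs_per_compound < 1 || pairs_per_compound > n_targets) {
    stop("pairs_per_compound must be in [1, n_targets]", call. = FALSE)
  }
  structure(as.list(environment()), class = "np_config")
}

compound_ids <- function(config) sprintf("NP%05d", seq_len(config$n_compounds))
target_ids <- function(config) sprintf("T%04d", seq_len(config$n_targets))
disease_ids <- function(config) sprintf("DIS%03d", seq_len(config$n_diseases))

# moment-matched marginal samplers; each returns exactly n draws with
# population mean equal to m
sample_marginal <- function(family, n, m, s) {
  if (s == 0) {
    return(rep(if (family %in% c("nbinom", "poisson")) round(m) else m, n))
  }
  switch(family,
    normal = stats::rnorm(n, m, s),
    lognormal = {
      sdlog <- sqrt(log(1 + s^2 / m^2))
      meanlog <- log(m) - sdlog^2 / 2
      stats::rlnorm(n, meanlog, sdlog)
    },
    nbinom = {
      if (s^2 > m) {
        stats::rnbinom(n, size = m^2 / (s^2 - m), mu = m)
      } else {
        stats::rpois(n, m)  # printed variance at/below mean
      }
    },
    beta = {
      v <- s^2
      if (v >= m * (1 - m)) stop("beta moments infeasible", call. = FALSE)
      a <- m * (m * (1 - m) / v - 1)
      stats::rbeta(n, a, a * (1 - m) / m)
    },
    stop("unknown family: ", family, call. = FALSE)
  )
}

#' Generate a synthetic descriptor table
#'
#' Draws each descriptor independently from a moment-matched marginal (see
#' [np_descriptor_params]), so sample means converge on the configured
#' means. Marginals are independent by design — the strong covariance among
#' real descriptors (heavier molecules carry more acceptors) is deliberately
#' not emulated.
#'
#' @param config [generator_config()] object.
#' @return list with `descriptors` (data frame: `id` plus the eight panel
#'   columns) and `truth` (the parameter table used).
#' @export
gen_descriptor_table <- function(config) {
  stopifnot(inherits(config, "np_config"))
  pars <- config$descriptor_params
  n <- config$n_compounds
  withr::with_seed(config$seed + 1L, {
    cols <- lapply(seq_len(nrow(pars)), function(i) {
      sample_marginal(pars$family[i], n, pars$mean[i], pars$sd[i])
    })
  })
  names(cols) <- pars$descriptor
  desc <- data.frame(id = compound_ids(config), cols,
                     stringsAsFactors = FALSE)
  list(descriptors = desc, truth = pars)
}

#' Curated molecule fixtures with hand-verified descriptor truth
#'
#' A small SMILES set pairing well-known natural products (staurosporine,
#' quercetin, genistein) with standard controls (ethanol, benzene,
#' caffeine, sugars, simple drugs) and structure-normalization cases (a
#' salt, an enantiomer pair). Truth columns hold hand-counted values;
#' `NA` marks values left unasserted.
#'
#' @return data frame: `id`, `name`, `smiles`, and truth columns `mw`,
#'   `hba`, `hbd`, `n_rings`, `n_rotatable`, `n_carbon`, `n_chiral_c`.
#' @export
gen_molecule_fixtures <- function() {
  data.frame(
    id = c("FIX01", "FIX02", "FIX03", "FIX04", "FIX05", "FIX06", "FIX07",
           "FIX08", "FIX09", "FIX10", "FIX11", "FIX12"),
    name = c("ethanol", "benzene", "quercetin", "genistein", "staurosporine",
             "beta-D-glucopyranose", "caffeine", "aspirin", "ibuprofen",
             "naphthalene", "(R)-alanine", "(S)-alanine"),
    smiles = c(
      "CCO",
      "c1ccccc1",
      "C1=CC(=C(C=C1C2=C(C(=O)C3=C(C=C(C=C3O2)O)O)O)O)O",
      "C1=CC(=CC=C1C2=COC3=CC(=CC(=C3C2=O)O)O)O",
      "C[C@@]12[C@@H]([C@@H](C[C@H](O1)N3C4=CC=CC=C4C5=C6C(=C7C8=CC=CC=C8N2C7=C53)CNC6=O)NC)OC",
      "OC[C@H]1O[C@@H](O)[C@H](O)[C@@H](O)[C@@H]1O",
      "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
      "CC(=O)Oc1ccccc1C(=O)O",
      "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
      "c1ccc2ccccc2c1",
      "C[C@@H](N)C(=O)O",
      "C[C@H](N)C(=O)O"),
    mw = c(46.07, 78.11, 302.24, 270.24, 466.53, 180.16, 194.19, 180.16,
           206.28, 128.17, 89.09, 89.09),
    hba = c(1L, 0L, 7L, 5L, 7L, 6L, 6L, 4L, 2L, 0L, 3L, 3L),
    hbd = c(1L, 0L, 5L, 3L, 2L, 5L, 0L, 1L, 1L, 0L, 3L, 3L),
    n_rings = c(0L, 1L, 3L, 3L, 8L, 1L, 2L, 1L, 1L, 2L, 0L, 0L),
    n_rotatable = c(0L, 0L, 1L, 1L, NA, 1L, 0L, 3L, 4L, 0L, 1L, 1L),
    n_carbon = c(2L, 6L, 15L, 15L, 28L, 6L, 8L, 9L, 13L, 10L, 3L, 3L),
    n_chiral_c = c(0L, 0L, 0L, 0L, 4L, 5L, 0L, 0L, 0L, 0L, 1L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Generate a scale-free bipartite interaction network
#'
#' Compound degrees are drawn from a truncated discrete power law
#' \eqn{P(k) \propto k^{-\gamma}}, \eqn{k = 1..}`degree_max`; each compound
#' then attaches to that many distinct targets chosen preferentially by
#' Zipf weights, producing heavy-tailed target degrees without parallel
#' edges. Every compound has degree >= 1. Scores are a truncated-normal
#' experimental affinity scale.
#'
#' @param config [generator_config()] object.
#' @return edge data frame: `compound_id`, `target_id`, `score`,
#'   `source = "experimental"`.
#' @export
gen_interaction_network <- function(config) {
  stopifnot(inherits(config, "np_config"))
  n_c <- config$n_compounds; n_t <- config$n_targets
  kmax <- config$degree_max
  withr::with_seed(config$seed + 2L, {
    pk <- (seq_len(kmax))^(-config$degree_exponent)
    deg <- sample.int(kmax, n_c, replace = TRUE, prob = pk)
    w <- (seq_len(n_t))^(-config$target_weight_exponent)
    w <- sample(w)  # detach weight rank from target id order
    tgt <- lapply(deg, function(k) sample.int(n_t, k, prob = w))
    scores <- pmax(0.1, stats::rnorm(sum(deg), config$interaction_score_mean,
                                     config$interaction_score_sd))
  })
  cid <- compound_ids(config); tid <- target_ids(config)
  data.frame(
    compound_id = rep(cid, deg),
    target_id = tid[unlist(tgt)],
    score = scores,
    source = "experimental",
    stringsAsFactors = FALSE
  )
}

#' Generate a docking-score table with planted strong binders
#'
#' Background scores follow a truncated normal (default mean 5, sd 1.5)
#' over a sparse set of compound-target pairs; a configured fraction of
#' compounds receives one planted binder scored uniformly in the planted
#' range (default 9-11), strictly above every reference-ligand score, so
#' planted pairs are admissible at the stringent cutoff by construction.
#'
#' @param config [generator_config()] object.
#' @return list: `scores` (edge data frame, `source = "docking"`),
#'   `reference` (`target_id`, `ref_score`), `truth` (planted pairs:
#'   `compound_id`, `target_id`, `score`).
#' @export
gen_docking_scores <- function(config) {
  stopifnot(inherits(config, "np_config"))
  n_c <- config$n_compounds; n_t <- config$n_targets
  m <- config$pairs_per_compound
  cid <- compound_ids(config); tid <- target_ids(config)
  withr::with_seed(config$seed + 3L, {
    ref <- pmin(config$reference_cap,
                pmax(0.1, stats::rnorm(n_t, config$reference_mean,
                                       config$reference_sd)))
    tgt <- unlist(lapply(seq_len(n_c), function(i) sample.int(n_t, m)))
    bg <- pmax(0.01, stats::rnorm(n_c * m, config$background_mean,
                                  config$background_sd))
    n_p <- round(config$planted_binder_fraction * n_c)
    planted_c <- if (n_p > 0) sort(sample.int(n_c, n_p)) else integer(0)
    planted_t <- if (n_p > 0) sample.int(n_t, n_p, replace = TRUE) else integer(0)
    planted_s <- stats::runif(n_p, config$planted_range[1],
                              config$planted_range[2])
  })
  scores <- rbind(
    data.frame(compound_id = rep(cid, each = m), target_id = tid[tgt],
               score = bg, source = "docking", stringsAsFactors = FALSE),
    data.frame(compound_id = cid[planted_c], target_id = tid[planted_t],
               score = planted_s, source = "docking", stringsAsFactors = FALSE)
  )
  list(scores = scores,
       reference = data.frame(target_id = tid, ref_score = ref,
                              stringsAsFactors = FALSE),
       truth = data.frame(compound_id = cid[planted_c],
                          target_id = tid[planted_t], score = planted_s,
                          stringsAsFactors = FALSE))
}

#' Generate a sparse target-disease map with a planted indication
#'
#' Each disease is linked to at least one target. One designated compound
#' is given planted admissible edges (scores in the planted range) to every
#' target of one designated disease, so an end-to-end run of the prediction
#' model has a known rank-1 answer.
#'
#' @param config [generator_config()] object.
#' @param docking output of [gen_docking_scores()]; regenerated from
#'   `config` when `NULL`, keeping the bundle a pure function of the
#'   config.
#' @return list: `links` (`target_id`, `disease`), `edges` (docking score
#'   table augmented with the planted edges), `reference`, `truth` (list
#'   with `compound_id`, `disease`, `target_ids`).
#' @export
gen_disease_map <- function(config, docking = NULL) {
  stopifnot(inherits(config, "np_config"))
  if (is.null(docking)) docking <- gen_docking_scores(config)
  n_t <- config$n_targets
  tid <- target_ids(config); did <- disease_ids(config)
  rng <- config$disease_targets_range
  withr::with_seed(config$seed + 4L, {
    sizes <- sample(seq(rng[1], rng[2]), config$n_diseases, replace = TRUE)
    sizes[1] <- max(3L, sizes[1])  # designated disease needs a target set
    links <- lapply(sizes, function(s) sample.int(n_t, min(s, n_t)))
    designated_compound <- sample.int(config$n_compounds, 1)
    planted_scores <- stats::runif(length(links[[1]]),
                                   config$planted_range[1],
                                   config$planted_range[2])
  })
  link_df <- data.frame(
    target_id = tid[unlist(links)],
    disease = rep(did, lengths(links)),
    stringsAsFactors = FALSE
  )
  dc <- compound_ids(config)[designated_compound]
  planted <- data.frame(compound_id = dc, target_id = tid[links[[1]]],
                        score = planted_scores, source = "docking",
                        stringsAsFactors = FALSE)
  list(links = link_df,
       edges = rbind(docking$scores, planted),
       reference = docking$reference,
       truth = list(compound_id = dc, disease = did[1],
                    target_ids = tid[links[[1]]]))
}
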