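# Synthetic IP-MS pull-down generator. Plants protein complexes, samples
# antibody-driven pull-down experiments from them with capture noise,
# cross-reacting antibodies, background identifications and sticky
# contaminants, and emits the matching ground truth (complex memberships,
# implied true PPIs, true DDIs via synthetic domain assignments, sticky
# list). Every other module is testable end-to-end against this ground
# truth without any external data.

#' Configuration for the synthetic pull-down generator
#'
#' Defaults describe a mid-sized aggregation study: 200 experiments over
#' 40 planted complexes of 3-25 members, pull-down lists of 30-200
#' proteins with an occasional heavy-tailed large list, imperfect capture,
#' cross-reacting antibodies, uniformly present sticky contaminants, and
#' overdispersed spectral counts driven by a lognormal per-protein
#' abundance factor.
#'
#' @param n_proteins total protein universe (complex members + sticky +
#'   background pool).
#' @param n_complexes number of planted complexes.
#' @param complex_size_range inclusive size range of planted complexes.
#' @param n_experiments number of pull-down experiments.
#' @param list_size_range target range of identified-list sizes; lists are
#'   padded/trimmed with background identifications to stay inside it,
#'   except for deliberate heavy-tail draws.
#' @param capture_probability probability that a member of a pulled
#'   complex is identified in that experiment.
#' @param background_rate per-experiment appearance probability of each
#'   background-pool protein.
#' @param n_sticky number of sticky (non-specific) contaminant proteins.
#' @param sticky_rate per-experiment appearance probability of each sticky
#'   protein.
#' @param antibody_crossreact_probability per-experiment probability that
#'   an antibody's off-target complexes are pulled down alongside its
#'   target. Each antibody carries a fixed set of potential off-target
#'   complexes (its cross-reacting secondary antigens), so repeated
#'   experiments with one antibody share the same off-targets when they
#'   fire.
#' @param spc_dispersion negative-binomial overdispersion of spectral
#'   counts (0 = Poisson-like).
#' @param heavy_tail_prob probability that an experiment is a promiscuous
#'   pull-down hitting many extra complexes, yielding an oversized list.
#' @param seed integer seed (mandatory).
#' @return Validated list of class `generator_config`.
#' @export
generator_config <- function(n_proteins = 1600,
                             n_complexes = 40,
                             complex_size_range = c(3, 25),
                             n_experiments = 200,
                             list_size_range = c(30, 200),
                             capture_probability = 0.8,
                             background_rate = 0.08,
                             n_sticky = 100,
                             sticky_rate = 0.8,
                             antibody_crossreact_probability = 0.25,
                             spc_dispersion = 0.5,
                             heavy_tail_prob = 0.02,
                             seed) {
  if (missing(seed)) stop_usage("a seed is required")
  cfg <- list(n_proteins = n_proteins, n_complexes = n_complexes,
              complex_size_range = complex_size_range,
              n_experiments = n_experiments,
              list_size_range = list_size_range,
              capture_probability = capture_probability,
              background_rate = background_rate,
              n_sticky = n_sticky, sticky_rate = sticky_rate,
              antibody_crossreact_probability = antibody_crossreact_probability,
              spc_dispersion = spc_dispersion,
              heavy_tail_prob = heavy_tail_prob,
              seed = as.integer(seed))
  probs <- c(capture_probability, background_rate, sticky_rate,
             antibody_crossreact_probability, heavy_tail_prob)
  if (any(probs < 0 | probs > 1))
    stop_usage("probabilities must lie in [0, 1]")
  if (length(complex_size_range) != 2 || complex_size_range[1] < 2 ||
      diff(complex_size_range) < 0)
    stop_usage("complex_size_range must be an ordered pair with min >= 2")
  if (length(list_size_range) != 2 || list_size_range[1] < 1 ||
      diff(list_size_range) < 0)
    stop_usage("list_size_range must be an ordered positive pair")
  if (n_proteins < 1 || n_complexes < 1 || n_experiments < 1 || n_sticky < 0)
    stop_usage("counts must be positive (n_sticky may be 0)")
  if (spc_dispersion < 0) stop_usage("spc_dispersion must be >= 0")
  structure(cfg, class = "generator_config")
}

nb_counts <- function(n, mu, dispersion) {
  if (dispersion <= 0) counts <- stats::rpois(n, mu)
  else counts <- stats::rnbinom(n, mu = mu, size = 1 / dispersion)
  pmax(1L, as.integer(counts))  # an identified protein has >= 1 spectrum
}

#' Generate a synthetic IP-MS study with planted ground truth
#'
#' Each experiment draws an antibody and pulls down its target complex;
#' with probability `antibody_crossreact_probability` the antibody's
#' fixed off-target complexes come down too (cross-reactivity). A random
#' member of the target complex is recorded as the bait. Members of
#' pulled complexes are identified with `capture_probability` and receive
#' negative-binomial spectral counts scaled by a per-protein lognormal
#' abundance factor; sticky proteins appear everywhere at `sticky_rate`
#' with high counts; background-pool proteins appear at `background_rate`
#' with low counts. List sizes are padded/trimmed with background
#' identifications into `list_size_range` (heavy-tail draws are exempt
#' from trimming). Synthetic domain annotations give each complex a
#' compatible domain pair carried by alternating members, so within-complex
#' interactions imply ground-truth domain-domain interactions; decoy
#' domains (occasionally duplicated within a protein) are added on top.
#'
#' @param config a [generator_config()].
#' @return List with elements `matrix` ([spc_matrix]), `experiments`
#'   ([experiment_table]), `annotation` (`domain_annotation`) and `truth`
#'   (class `ground_truth`: `complexes`, `true_ppis`, `true_ddis`,
#'   `sticky`, `config`).
#' @export
generate_ipms <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  set.seed(cfg$seed)
  sizes <- sample(seq(cfg$complex_size_range[1], cfg$complex_size_range[2]),
                  cfg$n_complexes, replace = TRUE)
  if (sum(sizes) + cfg$n_sticky > cfg$n_proteins)
    stop_usage("n_proteins too small for the requested complexes + sticky ",
               "(need >= ", sum(sizes) + cfg$n_sticky, ")")
  ids <- sprintf("P%04d", seq_len(cfg$n_proteins))
  perm <- sample(ids)
  cx_members <- split(perm[seq_len(sum(sizes))],
                      rep(seq_len(cfg$n_complexes), sizes))
  names(cx_members) <- sprintf("planted_%02d", seq_len(cfg$n_complexes))
  sticky <- sort(perm[sum(sizes) + seq_len(cfg$n_sticky)])
  background <- perm[-seq_len(sum(sizes) + cfg$n_sticky)]
  alpha <- stats::setNames(stats::rlnorm(cfg$n_proteins,
                                         meanlog = log(6), sdlog = 0.8), ids)
  mw <- stats::setNames(round(stats::runif(cfg$n_proteins, 10, 300), 1), ids)

  # each antibody has one target complex and a fixed set of potential
  # off-target complexes (cross-reacting secondary antigens); whether the
  # off-targets actually come down varies by experiment
  n_ab <- max(1L, ceiling(cfg$n_experiments / 2))
  # the study targets the complexes it surveys: every complex gets at
  # least one antibody when there are enough antibodies to go around
  ab_target <- c(sample(rep_len(seq_len(cfg$n_complexes),
                                min(n_ab, cfg$n_complexes))),
                 if (n_ab > cfg$n_complexes)
                   sample(cfg$n_complexes, n_ab - cfg$n_complexes,
                          replace = TRUE))
  ab_off <- lapply(seq_len(n_ab), function(i) {
    others <- setdiff(seq_len(cfg$n_complexes), ab_target[i])
    if (!length(others)) return(integer(0))
    others[sample.int(length(others), min(sample(1:2, 1), length(others)))]
  })

  m <- cfg$n_experiments
  eid <- sprintf("E%04d", seq_len(m))
  spc <- array(0L, dim = c(cfg$n_proteins, m), dimnames = list(ids, eid))
  bait <- character(m); antibody <- character(m)
  cell_line <- sample(c("HeLa", "MCF7", "HEK293"), m, replace = TRUE)
  condition <- sample(c("untreated", "stimulated"), m, replace = TRUE)
  lo <- cfg$list_size_range[1]; hi <- cfg$list_size_range[2]
  for (j in seq_len(m)) {
    abi <- sample.int(n_ab, 1)
    antibody[j] <- sprintf("AB%04d", abi)
    pulled <- ab_target[abi]
    if (stats::runif(1) < cfg$antibody_crossreact_probability)
      pulled <- c(pulled, ab_off[[abi]])
    heavy <- stats::runif(1) < cfg$heavy_tail_prob
    bait[j] <- sample(cx_members[[ab_target[abi]]], 1)
    members <- unique(unlist(cx_members[pulled], use.names = FALSE))
    cap <- members[stats::runif(length(members)) < cfg$capture_probability]
    cap <- unique(c(bait[j], cap))  # the bait itself is always recovered
    st <- sticky[stats::runif(length(sticky)) < cfg$sticky_rate]
    bg <- background[stats::runif(length(background)) < cfg$background_rate]
    n_now <- length(cap) + length(st) + length(bg)
    if (heavy) {
      # promiscuous pull-down: an oversized list padded with one-off
      # background identifications, up to 3x the nominal maximum
      target <- ceiling(stats::runif(1, hi, 3 * hi))
      pool <- setdiff(background, bg)
      bg <- c(bg, sample(pool, min(max(0, target - n_now), length(pool))))
    } else if (n_now < lo) {
      pool <- setdiff(background, bg)
      bg <- c(bg, sample(pool, min(lo - n_now, length(pool))))
    } else if (n_now > hi && length(bg)) {
      drop_n <- min(n_now - hi, length(bg))
      bg <- sample(bg, length(bg) - drop_n)
    }
    spc[cap, j] <- nb_counts(length(cap), alpha[cap], cfg$spc_dispersion)
    if (length(st))
      spc[st, j] <- nb_counts(length(st), 2 * alpha[st], cfg$spc_dispersion)
    if (length(bg))
      spc[bg, j] <- pmax(1L, as.integer(stats::rpois(length(bg), 0.6)))
  }

  mat <- spc_matrix(spc, mw)
  expts <- experiment_table(mat, bait = bait, antibody = antibody,
                            cell_line = cell_line, condition = condition)

  # synthetic domains: one compatible domain pair per complex, carried by
  # alternating members, plus decoys (sometimes duplicated)
  decoys <- sprintf("DEC%03d", seq_len(50))
  prot_dom <- list()
  true_ddis <- data.frame(domain_a = character(0), domain_b = character(0))
  for (k in seq_len(cfg$n_complexes)) {
    dA <- sprintf("CXD%03da", k); dB <- sprintf("CXD%03db", k)
    mem <- cx_members[[k]]
    side <- rep(c(dA, dB), length.out = length(mem))
    for (i in seq_along(mem))
      prot_dom[[mem[i]]] <- c(prot_dom[[mem[i]]], side[i])
    true_ddis <- rbind(true_ddis,
                       data.frame(domain_a = min(dA, dB),
                                  domain_b = max(dA, dB)))
  }
  for (p in ids) {
    extra <- sample(decoys, sample(1:2, 1))
    if (stats::runif(1) < 0.1) extra <- c(extra, extra[1])  # multiplicity
    prot_dom[[p]] <- c(prot_dom[[p]], extra)
  }
  annot <- domain_annotation(rep(names(prot_dom), lengths(prot_dom)),
                             unlist(prot_dom, use.names = FALSE))

  true_ppis <- do.call(rbind, lapply(cx_members, function(mem) {
    if (length(mem) < 2) return(NULL)
    cmb <- utils::combn(sort(mem), 2)
    data.frame(protein_a = cmb[1, ], protein_b = cmb[2, ],
               stringsAsFactors = FALSE)
  }))
  rownames(true_ppis) <- NULL
  class(true_ppis) <- c("pair_set", "data.frame")

  truth <- structure(list(complexes = cx_members, true_ppis = true_ppis,
                          true_ddis = true_ddis, sticky = sticky,
                          config = cfg),
                     class = "ground_truth")
  list(matrix = mat, experiments = expts, annotation = annot, truth = truth)
}

#' Subsample a ground-truth PPI set into an incomplete reference
#'
#' Literature reference sets are incomplete; this keeps each true
#' interaction independently with probability `fraction`, emulating that
#' incompleteness for evaluation tests.
#'
#' @param truth a `ground_truth` (from [generate_ipms()]) or a pair set.
#' @param fraction retention probability in \[0, 1\].
#' @param seed optional seed for the subsample.
#' @return A `pair_set` of retained interactions.
#' @export
degrade <- function(truth, fraction, seed = NULL) {
  if (!(fraction >= 0 && fraction <= 1))
    stop_usage("fraction must be in [0, 1]")
  ppis <- if (inherits(truth, "ground_truth")) truth$true_ppis else truth
  if (!is.null(seed)) set.seed(seed)
  keep <- stats::runif(nrow(ppis)) < fraction
  if (fraction == 1) keep <- rep(TRUE, nrow(ppis))
  out <- ppis[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pair_set", "data.frame")
  out
}
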