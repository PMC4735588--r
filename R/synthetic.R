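#' Configuration of a synthetic relapsing-remitting cohort
#'
#' Defines the study conditions the generator emulates: a cohort of patients
#' sampled once in relapse and once in remission plus matched healthy
#' controls, with sex-specific planted differential expression and a set of
#' probes planted with opposite-direction ("mirror") effects in the two
#' phases relative to controls.
#'
#' @param n_patients patients (two samples each). Default 24.
#' @param n_controls healthy controls (one sample each). Default 24.
#' @param n_probes probes on the array. Default 600.
#' @param frac_mirna fraction of probes annotated miRNA (rest snoRNA).
#' @param sex_ratio fraction of females among patients and controls.
#' @param n_de_relapse_f planted relapse-vs-remission DE probes in females.
#' @param n_de_remission_f planted remission-vs-control DE probes in females.
#' @param n_de_remission_m planted remission-vs-control DE probes in males.
#' @param n_mirror probes planted with opposite-direction effects in the two
#'   phases (subset of both female DE sets);
#'   must not exceed `min(n_de_relapse_f, n_de_remission_f)`.
#' @param effect_log2 mean absolute planted log2 fold change. Default 1.5.
#' @param patient_sd between-patient SD on the log2 scale.
#' @param noise_sd residual SD on the log2 scale.
#' @param detect_floor log2 intensity below which a probe-sample pair is
#'   called not detected.
#' @param n_same_treatment patients receiving the same treatment in both
#'   phases (eligible for the paired relapse-vs-remission analysis);
#'   defaults to all patients.
#' @param seed integer seed.
#' @return a validated `CohortConfig` list.
#' @export
cohort_config <- function(n_patients = 24, n_controls = 24, n_probes = 600,
                          frac_mirna = 0.5, sex_ratio = 0.7,
                          n_de_relapse_f = 20, n_de_remission_f = 20,
                          n_de_remission_m = 5, n_mirror = 8,
                          effect_log2 = 1.5, patient_sd = 0.5, noise_sd = 0.3,
                          detect_floor = 7, n_same_treatment = n_patients,
                          seed = 1L) {
  cfg <- list(
    n_patients = check_count(n_patients, "n_patients", min = 2L),
    n_controls = check_count(n_controls, "n_controls", min = 2L),
    n_probes = check_count(n_probes, "n_probes", min = 2L),
    frac_mirna = check_fraction(frac_mirna, "frac_mirna"),
    sex_ratio = check_fraction(sex_ratio, "sex_ratio"),
    n_de_relapse_f = check_count(n_de_relapse_f, "n_de_relapse_f"),
    n_de_remission_f = check_count(n_de_remission_f, "n_de_remission_f"),
    n_de_remission_m = check_count(n_de_remission_m, "n_de_remission_m"),
    n_mirror = check_count(n_mirror, "n_mirror"),
    effect_log2 = if (effect_log2 < 0) stop_field("effect_log2", "must be >= 0")
                  else effect_log2,
    patient_sd = if (patient_sd < 0) stop_field("patient_sd", "must be >= 0")
                 else patient_sd,
    noise_sd = if (noise_sd < 0) stop_field("noise_sd", "must be >= 0")
               else noise_sd,
    detect_floor = detect_floor,
    n_same_treatment = check_count(n_same_treatment, "n_same_treatment"),
    seed = check_count(seed, "seed")
  )
  if (cfg$n_mirror > min(cfg$n_de_relapse_f, cfg$n_de_remission_f))
    stop_field("n_mirror",
               "must not exceed min(n_de_relapse_f, n_de_remission_f)")
  if (cfg$n_same_treatment > cfg$n_patients)
    stop_field("n_same_treatment", "must not exceed n_patients")
  structure(cfg, class = "CohortConfig")
}

#' Simulate a relapsing-remitting cohort with planted ground truth
#'
#' Intensity model on the log2 scale: probe baseline `Normal(8, 2)` +
#' patient random effect `Normal(0, patient_sd)` (shared by the two samples
#' of a patient) + planted effect + residual `Normal(0, noise_sd)`.
#' Planted DE probes shift by `±effect_log2` in the designated stratum:
#' relapse-signature probes shift transiently (relapse samples only),
#' remission-signature probes shift persistently (both phases, so the
#' remission-vs-control comparison sees them but relapse-vs-remission does
#' not), and mirror probes shift `+effect_log2` in one phase and
#' `-effect_log2` in the other, relative to controls, alternating which
#' phase is up. Effects are planted only on
#' probes whose baseline sits at least one log2 unit above `detect_floor`,
#' since differential expression is only observable for expressed probes.
#' Detection calls are `intensity > detect_floor`. Each planted miRNA probe
#' also receives target genes with anti-correlated mRNA fold changes,
#' recorded as `regulation_pairs` and `gene_fc` in the truth object.
#'
#' @param config a [cohort_config()].
#' @return list with `experiment` (an [expression_experiment()]) and `truth`
#'   (a `SyntheticTruth`: `de_membership` — named list of
#'   direction-by-probe vectors keyed `"relapse.females"`,
#'   `"remission.females"`, `"remission.males"`; `mirror_set`;
#'   `regulation_pairs` data.frame; `gene_fc` named vector; `planted_fc`
#'   named vector of planted linear fold changes for qPCR emulation).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    probes <- sprintf("probe_%04d", seq_len(cfg$n_probes))
    n_mir <- round(cfg$frac_mirna * cfg$n_probes)
    probe_meta <- data.frame(
      probe = probes,
      class = c(rep("miRNA", n_mir), rep("snoRNA", cfg$n_probes - n_mir)),
      human = TRUE, stringsAsFactors = FALSE)

    # design: patients (relapse + remission) and controls
    pat_ids <- sprintf("P%02d", seq_len(cfg$n_patients))
    ctl_ids <- sprintf("C%02d", seq_len(cfg$n_controls))
    n_f_pat <- round(cfg$sex_ratio * cfg$n_patients)
    n_f_ctl <- round(cfg$sex_ratio * cfg$n_controls)
    pat_sex <- c(rep("F", n_f_pat), rep("M", cfg$n_patients - n_f_pat))
    ctl_sex <- c(rep("F", n_f_ctl), rep("M", cfg$n_controls - n_f_ctl))
    same_trt <- seq_len(cfg$n_patients) <= cfg$n_same_treatment
    design <- rbind(
      data.frame(sample = paste0(pat_ids, "_rel"), patient = pat_ids,
                 phase = "relapse", sex = pat_sex,
                 treatment = ifelse(same_trt, "IFN", "GA"),
                 stringsAsFactors = FALSE),
      data.frame(sample = paste0(pat_ids, "_rem"), patient = pat_ids,
                 phase = "remission", sex = pat_sex,
                 treatment = "IFN", stringsAsFactors = FALSE),
      data.frame(sample = ctl_ids, patient = ctl_ids, phase = "control",
                 sex = ctl_sex, treatment = "none", stringsAsFactors = FALSE))

    baseline <- stats::rnorm(cfg$n_probes, mean = 8, sd = 2)
    names(baseline) <- probes
    # plant only on expressed probes (baseline comfortably above the floor)
    expressed <- probes[baseline >= cfg$detect_floor + 1]
    n_planted <- cfg$n_de_relapse_f + cfg$n_de_remission_f + cfg$n_de_remission_m
    if (length(expressed) < n_planted)
      stop("too few expressed probes to plant the configured effects",
           call. = FALSE)
    picks <- sample(expressed, n_planted)
    mirror_set <- if (cfg$n_mirror) picks[seq_len(cfg$n_mirror)] else character()
    # mirror probes belong to both female signatures
    de_rel_f <- picks[seq_len(cfg$n_de_relapse_f)]
    rest <- setdiff(picks, de_rel_f)
    de_rem_f <- c(mirror_set,
                  rest[seq_len(cfg$n_de_remission_f - cfg$n_mirror)])
    de_rem_m <- setdiff(rest, de_rem_f)[seq_len(cfg$n_de_remission_m)]

    sgn <- function(ids) {
      if (!length(ids)) return(stats::setNames(numeric(), character()))
      stats::setNames(rep_len(c(1, -1), length(ids)), ids)
    }
    # mirror probes: +effect in relapse, -effect in remission (vs control),
    # alternating orientation probe by probe
    mirror_sign <- sgn(mirror_set)
    rel_sign <- sgn(de_rel_f); rel_sign[mirror_set] <- mirror_sign
    rem_sign <- sgn(de_rem_f); rem_sign[mirror_set] <- -mirror_sign
    rem_m_sign <- sgn(de_rem_m)

    e <- cfg$effect_log2
    delta <- matrix(0, cfg$n_probes, nrow(design),
                    dimnames = list(probes, design$sample))
    female_pat <- design$sex == "F" & design$phase != "control"
    male_pat <- design$sex == "M" & design$phase != "control"
    rel_f <- design$sample[female_pat & design$phase == "relapse"]
    rem_f <- design$sample[female_pat & design$phase == "remission"]
    rel_m <- design$sample[male_pat & design$phase == "relapse"]
    rem_m <- design$sample[male_pat & design$phase == "remission"]
    add <- function(signs, cols) {
      ids <- names(signs)
      if (length(ids) && length(cols))
        delta[ids, cols] <<- delta[ids, cols] + signs * e
    }
    # relapse-signature probes: transient shift in relapse samples only;
    # remission-signature (non-mirror) probes: persistent shift in both
    # phases, so they stay out of the relapse-vs-remission list; mirror
    # probes: opposite shifts in the two phases relative to controls
    rel_only <- rel_sign[setdiff(names(rel_sign), mirror_set)]
    rem_only <- rem_sign[setdiff(names(rem_sign), mirror_set)]
    add(rel_only, rel_f)
    add(rem_only, rel_f); add(rem_only, rem_f)
    add(mirror_sign, rel_f); add(-mirror_sign, rem_f)
    add(rem_m_sign, rel_m); add(rem_m_sign, rem_m)

    patient_eff <- stats::rnorm(length(unique(design$patient)), 0, cfg$patient_sd)
    names(patient_eff) <- unique(design$patient)
    noise <- matrix(stats::rnorm(cfg$n_probes * nrow(design), 0, cfg$noise_sd),
                    cfg$n_probes, nrow(design))
    intensities <- baseline + delta +
      matrix(patient_eff[design$patient], cfg$n_probes, nrow(design),
             byrow = TRUE) + noise
    dimnames(intensities) <- list(probes, design$sample)
    detected <- intensities > cfg$detect_floor

    # planted anti-correlated target genes for every planted miRNA probe
    planted_mirna <- intersect(unique(c(de_rel_f, de_rem_f, de_rem_m)),
                               probe_meta$probe[probe_meta$class == "miRNA"])
    all_sign <- c(rel_sign, rem_sign[setdiff(names(rem_sign), names(rel_sign))],
                  rem_m_sign)
    regulation_pairs <- NULL
    gene_fc <- numeric()
    if (length(planted_mirna)) {
      per_mirna <- 3L
      genes <- sprintf("GENE%04d", seq_len(length(planted_mirna) * per_mirna))
      regulation_pairs <- data.frame(
        mirna = rep(planted_mirna, each = per_mirna), gene = genes,
        stringsAsFactors = FALSE)
      gene_fc <- stats::setNames(
        -all_sign[regulation_pairs$mirna] *
          stats::runif(nrow(regulation_pairs), 0.5, 2),
        regulation_pairs$gene)
    } else {
      regulation_pairs <- data.frame(mirna = character(), gene = character(),
                                     stringsAsFactors = FALSE)
    }

    truth <- structure(list(
      de_membership = list(
        relapse.females = stats::setNames(
          ifelse(rel_sign > 0, "up", "down"), names(rel_sign)),
        remission.females = stats::setNames(
          ifelse(rem_sign > 0, "up", "down"), names(rem_sign)),
        remission.males = stats::setNames(
          ifelse(rem_m_sign > 0, "up", "down"), names(rem_m_sign))),
      mirror_set = mirror_set,
      regulation_pairs = regulation_pairs,
      gene_fc = gene_fc,
      planted_fc = 2^(all_sign * e)
    ), class = "SyntheticTruth")

    list(experiment = expression_experiment(intensities, detected, design,
                                            probe_meta),
         truth = truth)
  })
}

#' Simulate a miRNA-target prediction table with decoys
#'
#' True planted regulation pairs receive at least 3 supporting sources and a
#' standard score of at least 40 (Uniform(40, 100)), so they survive the
#' prediction filters; decoy pairs sample `n_sources` uniformly on {1..12}
#' and scores uniformly on [0, 100], so a known fraction fails each filter.
#'
#' @param truth a `SyntheticTruth` with non-empty `regulation_pairs`.
#' @param n_decoys number of decoy rows (>= 0).
#' @param seed integer seed.
#' @return data.frame (`mirna`, `gene`, `n_sources`, `score`, `is_true`).
#' @export
simulate_predictions <- function(truth, n_decoys = 100, seed = 1L) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  if (n_decoys < 0) stop("n_decoys must be >= 0", call. = FALSE)
  pairs <- truth$regulation_pairs
  if (!nrow(pairs)) stop("truth has no regulation pairs", call. = FALSE)
  withr::with_seed(seed, {
    true_rows <- data.frame(
      mirna = pairs$mirna, gene = pairs$gene,
      n_sources = sample(3:12, nrow(pairs), replace = TRUE),
      score = stats::runif(nrow(pairs), 40, 100),
      is_true = TRUE, stringsAsFactors = FALSE)
    if (n_decoys > 0) {
      decoy_rows <- data.frame(
        mirna = sample(unique(pairs$mirna), n_decoys, replace = TRUE),
        gene = sprintf("DECOY%04d", seq_len(n_decoys)),
        n_sources = sample(1:12, n_decoys, replace = TRUE),
        score = stats::runif(n_decoys, 0, 100),
        is_true = FALSE, stringsAsFactors = FALSE)
      rbind(true_rows, decoy_rows)
    } else true_rows
  })
}

#' Simulate a qPCR plate recovering planted fold changes
#'
#' Generates replicate CT values for a case and a reference group such that
#' the 2^-ddCT method recovers each planted fold change in expectation.
#' Two endogenous-control assays (RNU48- and U6-like) are included in every
#' sample.
#'
#' @param truth_fold_changes named numeric vector of planted linear fold
#'   changes (> 0), named by assay/probe id.
#' @param n_replicates replicate wells per (sample, assay). Default 3.
#' @param ct_sd per-well CT noise SD in cycles (>= 0).
#' @param seed integer seed.
#' @param n_per_group samples per group. Default 6.
#' @return list with `plate` (replicate-level data.frame: `sample`, `assay`,
#'   `replicate`, `ct`, `is_control`) and `design` (`sample`, `group` with
#'   groups `"case"` and `"reference"`).
#' @export
simulate_qpcr <- function(truth_fold_changes, n_replicates = 3, ct_sd = 0.2,
                          seed = 1L, n_per_group = 6) {
  if (any(truth_fold_changes <= 0))
    stop("fold changes must be > 0", call. = FALSE)
  if (is.null(names(truth_fold_changes)))
    stop("truth_fold_changes must be named by assay id", call. = FALSE)
  if (ct_sd < 0) stop("ct_sd must be >= 0", call. = FALSE)
  n_replicates <- check_count(n_replicates, "n_replicates", min = 1L)

  samples <- c(paste0("case_", seq_len(n_per_group)),
               paste0("ref_", seq_len(n_per_group)))
  groups <- rep(c("case", "reference"), each = n_per_group)
  assays <- names(truth_fold_changes)
  controls <- c("RNU48", "U6")

  withr::with_seed(seed, {
    rows <- list()
    for (i in seq_along(samples)) {
      is_case <- groups[i] == "case"
      for (ctl in controls) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = samples[i], assay = ctl,
          replicate = seq_len(n_replicates),
          ct = 20 + stats::rnorm(n_replicates, 0, ct_sd),
          is_control = TRUE, stringsAsFactors = FALSE)
      }
      for (a in assays) {
        # lower CT = higher expression; case shifted by -log2(FC)
        mu <- 25 - if (is_case) log2(truth_fold_changes[[a]]) else 0
        rows[[length(rows) + 1L]] <- data.frame(
          sample = samples[i], assay = a,
          replicate = seq_len(n_replicates),
          ct = mu + stats::rnorm(n_replicates, 0, ct_sd),
          is_control = FALSE, stringsAsFactors = FALSE)
      }
    }
    list(plate = do.call(rbind, rows),
         design = data.frame(sample = samples, group = groups,
                             stringsAsFactors = FALSE))
  })
}

#' Simulate a gene-set collection with one planted enriched term
#'
#' One term is drawn from a designated query set so it overlaps the query
#' far above chance; the remaining terms are random draws from the
#' universe.
#'
#' @param universe character vector: the gene universe (background).
#' @param n_terms total number of terms (>= 1).
#' @param enriched_term_genes character vector: the planted term's genes
#'   (draw them from your query set).
#' @param seed integer seed.
#' @param term_size size of the random terms. Default 15.
#' @return named list of gene sets; the planted term is named
#'   `"planted_term"`, with term descriptions in attribute `descriptions`.
#' @export
simulate_genesets <- function(universe, n_terms = 20, enriched_term_genes,
                              seed = 1L, term_size = 15) {
  n_terms <- check_count(n_terms, "n_terms", min = 1L)
  if (!length(enriched_term_genes))
    stop("enriched_term_genes must be non-empty", call. = FALSE)
  withr::with_seed(seed, {
    sets <- list(planted_term = unique(enriched_term_genes))
    for (i in seq_len(n_terms - 1L)) {
      sets[[sprintf("random_term_%02d", i)]] <-
        sample(universe, min(term_size, length(universe)))
    }
    attr(sets, "descriptions") <- stats::setNames(
      c("planted enriched term",
        rep("random background term", n_terms - 1L)), names(sets))
    sets
  })
}
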