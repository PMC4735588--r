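# Hand-built miniature experiment: 2 patients (relapse + remission),
# 2 controls, all female unless sexes given.
tiny_experiment <- function(intensities, detected = NULL, sexes = NULL) {
  n <- nrow(intensities)
  samples <- c("P1_rel", "P2_rel", "P1_rem", "P2_rem", "C1", "C2")
  stopifnot(ncol(intensities) == length(samples))
  dimnames(intensities) <- list(sprintf("p%02d", seq_len(n)), samples)
  if (is.null(detected)) detected <- intensities > -Inf
  dimnames(detected) <- dimnames(intensities)
  design <- data.frame(
    sample = samples,
    patient = c("P1", "P2", "P1", "P2", "C1", "C2"),
    phase = c("relapse", "relapse", "remission", "remission", "control", "control"),
    sex = sexes %||% rep("F", 6),
    treatment = c("IFN", "IFN", "IFN", "IFN", "none", "none"),
    stringsAsFactors = FALSE)
  expression_experiment(intensities, detected, design)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic prediction records
make_predictions <- function(n, seed = 1) {
  withr::with_seed(seed, data.frame(
    mirna = sample(paste0("mir", 1:8), n, replace = TRUE),
    gene = sample(paste0("G", 1:40), n, replace = TRUE),
    n_sources = sample(1:12, n, replace = TRUE),
    score = runif(n, 0, 100),
    stringsAsFactors = FALSE))
}
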