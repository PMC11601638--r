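#' Simulate case/control microbial profiles with planted biomarkers
#'
#' Generates a synthetic relative-abundance dataset emulating a
#' case/control shotgun-metagenomics cohort: a small set of informative
#' species whose presence probability differs between classes (planted
#' discriminative biomarkers, like the prevalence contrasts seen for
#' CRC-associated species) plus uninformative background species present in
#' both classes at the same rate. Presence is Bernoulli per species and
#' class; the magnitude of present species is log-normal (heavy-tailed,
#' like real relative abundances) and every sample is renormalized so that
#' species plus an unclassified remainder sum to exactly 100.
#'
#' Sex is assigned uniformly and age uniformly over 28-84 years; the
#' metadata carries no abundance effect, so stratified analyses of
#' simulated data behave like the unstratified one apart from sample size.
#'
#' @param n_case,n_control Samples per class (defaults 60/60).
#' @param n_species Total species count (default 30).
#' @param n_informative Number of planted discriminative species
#'   (default 3).
#' @param prev_case,prev_control Presence probability of informative
#'   species in case and control samples (defaults 0.8 and 0.1).
#' @param prev_background Presence probability of the remaining species in
#'   both classes (default 0.5).
#' @param meanlog,sdlog Log-normal parameters of the raw magnitude of a
#'   present species (defaults 0 and 1).
#' @param unclassified_meanlog,unclassified_sdlog Log-normal parameters of
#'   the raw unclassified mass (defaults `log(30)` and 0.5), setting how
#'   much of each sample the named species leave unexplained.
#' @param class_labels Labels for the two classes
#'   (default `c("case", "control")`).
#' @param seed Optional seed; the same seed reproduces the dataset exactly.
#'
#' @return A list with `profiles` (a [profile_dataset()] of relative
#'   abundances with labels, unclassified remainder and metadata) and
#'   `informative` (the planted species names).
#'
#' @examples
#' sim <- simulate_profiles(n_case = 10, n_control = 10, n_species = 12,
#'                          seed = 42)
#' sim$informative
#' range(rowSums(sim$profiles$abundance) + sim$profiles$unclassified)  # 100
#' @export
simulate_profiles <- function(n_case = 60, n_control = 60, n_species = 30,
                              n_informative = 3, prev_case = 0.8,
                              prev_control = 0.1, prev_background = 0.5,
                              meanlog = 0, sdlog = 1,
                              unclassified_meanlog = log(30),
                              unclassified_sdlog = 0.5,
                              class_labels = c("case", "control"),
                              seed = NULL) {
  if (n_informative > n_species)
    stop("n_informative cannot exceed n_species")
  probs <- c(prev_case, prev_control, prev_background)
  if (any(probs < 0 | probs > 1))
    stop("presence probabilities must be in [0, 1]")
  if (n_case < 1 || n_control < 1) stop("both classes need at least 1 sample")
  if (length(class_labels) != 2L || anyDuplicated(class_labels))
    stop("class_labels must be two distinct labels")

  n <- n_case + n_control
  wi <- max(nchar(n_species), 2L)
  species <- c(
    if (n_informative > 0)
      sprintf("s__Planted_species_%0*d", wi, seq_len(n_informative)),
    if (n_species > n_informative)
      sprintf("s__Background_species_%0*d", wi,
              seq_len(n_species - n_informative)))
  sample_ids <- sprintf("sample_%03d", seq_len(n))
  labels <- rep(class_labels, c(n_case, n_control))

  with_seed(seed, {
    p <- matrix(prev_background, nrow = n, ncol = n_species)
    if (n_informative > 0) {
      p[labels == class_labels[1L], seq_len(n_informative)] <- prev_case
      p[labels == class_labels[2L], seq_len(n_informative)] <- prev_control
    }
    present <- matrix(rbinom(n * n_species, 1L, as.vector(p)),
                      nrow = n, ncol = n_species)
    mag <- matrix(rlnorm(n * n_species, meanlog, sdlog),
                  nrow = n, ncol = n_species) * present
    uncl_raw <- rlnorm(n, unclassified_meanlog, unclassified_sdlog)
    total <- rowSums(mag) + uncl_raw
    abundance <- 100 * mag / total
    unclassified <- 100 * uncl_raw / total
    dimnames(abundance) <- list(sample_ids, species)
    metadata <- data.frame(
      sample_id = sample_ids,
      class = labels,
      sex = sample(c("male", "female"), n, replace = TRUE),
      age = sample(28:84, n, replace = TRUE),
      study = "synthetic",
      stringsAsFactors = FALSE)
    list(
      profiles = profile_dataset(abundance, labels = labels,
                                 unclassified = unclassified,
                                 metadata = metadata),
      informative = species[seq_len(n_informative)])
  })
}
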