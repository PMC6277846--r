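#' Planted ground-truth effect registry
#'
#' The registry of features with known transcript and protein
#' fold-changes (La over Ca) used by the count and spectral-count
#' generators and recovered by the analysis stages. Defaults encode the
#' hallmark responses of the lanthanide switch: *xoxF* up fourfold at
#' the transcript level (about twofold at the protein level), the
#' formaldehyde-activating enzyme *fae2* up 14-fold, a putative sulfate
#' transporter up 70-fold, the *fds2* formate-dehydrogenase operon up
#' 3-fold, the *mxaF/mxaI/mxaG* cluster strongly down (default 1/20 at
#' both levels; the printed record only calls it "tremendous"), and the
#' candidate XoxF cytochrome *xoxG4* down 1.5-fold in transcript with no
#' protein change. All other features are 1x.
#'
#' @param extra Optional `data.frame` with columns `feature_id`,
#'   `transcript_fc`, `protein_fc` appended to (or overriding) the
#'   defaults.
#' @return `data.frame` with columns `feature_id`, `transcript_fc`,
#'   `protein_fc`, `direction`.
#' @export
default_effect_registry <- function(extra = NULL) {
  reg <- data.frame(
    feature_id = c("xoxF", "fae2", "sulfate_transporter",
                   "fds2D", "fds2C", "fds2A",
                   "mxaF", "mxaI", "mxaG", "xoxG4"),
    transcript_fc = c(4, 14, 70, 3, 3, 3, 1/20, 1/20, 1/20, 1/1.5),
    protein_fc = c(2.5, 3, 3, 1.5, 1.5, 1.5, 1/20, 1/20, 1/20, 1),
    stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    stopifnot(all(c("feature_id", "transcript_fc", "protein_fc") %in%
                    names(extra)))
    reg <- reg[!reg$feature_id %in% extra$feature_id, ]
    reg <- rbind(reg, extra[, c("feature_id", "transcript_fc",
                                "protein_fc")])
  }
  if (any(reg$transcript_fc <= 0) || any(reg$protein_fc <= 0))
    stop("fold-changes must be > 0")
  reg$direction <- ifelse(reg$transcript_fc > 1, "up",
                          ifelse(reg$transcript_fc < 1, "down", "flat"))
  reg
}

#' Planted metabolite direction pattern
#'
#' Directions of metabolite pool changes in La-grown versus Ca-grown
#' cells: RuMP-pathway intermediates and the first TCA steps drop, while
#' downstream TCA intermediates stay flat and TCA-derived amino acids,
#' glycerate and agmatine rise.
#'
#' @return `data.frame` with columns `metabolite`, `direction`
#'   (`down`/`flat`/`up`).
#' @export
default_metabolite_pattern <- function() {
  data.frame(
    metabolite = c("sedoheptulose_7P", "fructose_6P", "glucose_6P",
                   "PEP", "glycerate_3P", "citrate", "aconitate",
                   "fumarate", "malate", "succinate",
                   "glutamate", "glutamine", "asparagine", "ectoine",
                   "glycerate", "agmatine"),
    direction = c(rep("down", 7), rep("flat", 3), rep("up", 6)),
    stringsAsFactors = FALSE)
}

#' Simulate a chemostat off-gas series
#'
#' Generates outlet gas percentages consistent with the condition's
#' planted physiology: the CH4 consumption implied by the biomass
#' concentration, dilution rate, culture volume and biomass yield; O2
#' consumption as `planted_ratio` times the molar CH4 consumption; CO2
#' production as CH4 consumption minus biomass carbon (0.5 g C per
#' g DCW). Gaussian noise with `noise_sd_pct` percent-unit standard
#' deviation is added to every outlet reading. The planted ground truth
#' is attached as attribute `"truth"`; analysis code never reads it.
#'
#' @param spec A [condition_spec()].
#' @param yield_biomass Planted biomass yield, g DCW per g CH4.
#' @param planted_ratio Planted O2:CH4 molar consumption ratio, in
#'   `[1, 2]`.
#' @param duration_h,dt_h Length and step of the series (default 24 h
#'   at 0.5 h).
#' @param noise_sd_pct Gaussian noise sd on outlet percentages, in
#'   percent (v/v) units (default 1).
#' @param seed Integer seed; the series is deterministic given
#'   (parameters, seed).
#' @return `data.frame` with columns `time_h`, `ch4_out_pct`,
#'   `o2_out_pct`, `co2_out_pct` and attribute `truth` (list with the
#'   planted values).
#' @examples
#' cond <- default_conditions()$la_optimal
#' og <- simulate_offgas(cond$spec, cond$yield_biomass, 1.28, seed = 1)
#' steady_state_summary(cond$spec, og)$ratio_o2_ch4
#' @export
simulate_offgas <- function(spec, yield_biomass, planted_ratio,
                            duration_h = 24, dt_h = 0.5,
                            noise_sd_pct = 1, seed = 1) {
  stopifnot(inherits(spec, "reeflux_condition"), yield_biomass > 0,
            planted_ratio >= 1, planted_ratio <= 2, noise_sd_pct >= 0,
            duration_h > 0, dt_h > 0)
  ch4_g_h <- spec$biomass_conc * spec$dilution_rate *
    spec$culture_volume / yield_biomass
  ch4_mol_h <- ch4_g_h / CH4_MOLAR_MASS
  o2_mol_h <- planted_ratio * ch4_mol_h
  co2_mol_h <- max(ch4_mol_h -
                     spec$biomass_conc * spec$dilution_rate *
                     spec$culture_volume * 0.5 / 12.011, 0)
  to_pct <- function(mol_h) mol_h * MOLAR_VOLUME_L / spec$gas_flow * 100
  ch4_out <- spec$inlet_ch4_pct - to_pct(ch4_mol_h)
  o2_out <- spec$inlet_o2_pct - to_pct(o2_mol_h)
  co2_out <- to_pct(co2_mol_h)
  if (ch4_out < 0 || o2_out < 0)
    stop("parameter error: implied outlet percentage below zero ",
         "(increase gas_flow or inlet percentage)")
  times <- seq(0, duration_h, by = dt_h)
  set.seed(seed)
  n <- length(times)
  out <- data.frame(
    time_h = times,
    ch4_out_pct = ch4_out + stats::rnorm(n, 0, noise_sd_pct),
    o2_out_pct = o2_out + stats::rnorm(n, 0, noise_sd_pct),
    co2_out_pct = co2_out + stats::rnorm(n, 0, noise_sd_pct))
  attr(out, "truth") <- list(
    yield_biomass = yield_biomass, ratio_o2_ch4 = planted_ratio,
    ch4_out_pct = ch4_out, o2_out_pct = o2_out, co2_out_pct = co2_out,
    ch4_mmol_h = ch4_mol_h * 1000, o2_mmol_h = o2_mol_h * 1000,
    seed = seed, noise_sd_pct = noise_sd_pct)
  out
}

#' Simulate an RNA-seq count table with planted effects
#'
#' Negative-binomial counts for two conditions (Ca, La) with
#' `reps_per_condition` replicates each. Baseline (Ca) means are drawn
#' log-uniformly and scaled to the target library depth; La means are
#' the Ca means times the registry's transcript fold-changes. Registry
#' features occupy the first rows under their own ids; all other
#' features are unchanged (fold-change 1). `dispersion = 0` reduces to
#' Poisson noise.
#'
#' @param n_features Total features (>= registry rows).
#' @param registry A [default_effect_registry()]-shaped `data.frame`.
#' @param reps_per_condition Replicates per condition (default 2).
#' @param depth Expected total counts per sample (default 2e6).
#' @param dispersion Negative-binomial dispersion (default 0.05).
#' @param seed Integer seed.
#' @return List with `counts` (matrix, columns `Ca_1..`, `La_1..`),
#'   `condition` (column labels) and `truth` (`data.frame` of planted
#'   per-feature fold-changes).
#' @export
simulate_counts <- function(n_features = 3000,
                            registry = default_effect_registry(),
                            reps_per_condition = 2, depth = 2e6,
                            dispersion = 0.05, seed = 1) {
  stopifnot(n_features >= nrow(registry), dispersion >= 0, depth > 0,
            reps_per_condition >= 1)
  set.seed(seed)
  fc <- rep(1, n_features)
  nreg <- nrow(registry)
  ids <- c(registry$feature_id,
           sprintf("gene_%04d", seq_len(n_features - nreg)))
  fc[seq_len(nreg)] <- registry$transcript_fc
  # bulk expression spans ~4 orders of magnitude; the hallmark
  # methanol-oxidation genes are well expressed in methanotrophs, so
  # registry features draw from the upper decades
  base <- exp(stats::runif(n_features, log(2), log(50000)))
  base[seq_len(nreg)] <- exp(stats::runif(nreg, log(500), log(5000)))
  base <- base / sum(base) * depth
  if (max(fc) * max(base) / depth > 0.5)
    warning("depth too small to express the largest planted effects")
  mu <- cbind(matrix(rep(base, reps_per_condition), ncol = reps_per_condition),
              matrix(rep(base * fc, reps_per_condition),
                     ncol = reps_per_condition))
  counts <- matrix(0L, n_features, 2 * reps_per_condition)
  for (j in seq_len(ncol(mu))) {
    counts[, j] <- if (dispersion == 0)
      stats::rpois(n_features, mu[, j])
    else
      stats::rnbinom(n_features, mu = mu[, j], size = 1 / dispersion)
  }
  condition <- rep(c("Ca", "La"), each = reps_per_condition)
  colnames(counts) <- paste(condition,
                            rep(seq_len(reps_per_condition), 2),
                            sep = "_")
  rownames(counts) <- ids
  list(counts = counts, condition = condition,
       truth = data.frame(feature_id = ids, fold_change = fc,
                          base_mean = base, stringsAsFactors = FALSE))
}

#' Simulate a spectral-count proteomics table
#'
#' Poisson spectral counts per protein and replicate; La means are the
#' Ca means times the registry's protein fold-changes.
#'
#' @param n_proteins Total proteins (>= registry rows).
#' @param registry A [default_effect_registry()]-shaped `data.frame`.
#' @param reps Replicates per condition (default 3).
#' @param mean_count Mean Ca-condition spectral count (default 60).
#' @param seed Integer seed.
#' @return List with `counts`, `condition`, `truth` as in
#'   [simulate_counts()].
#' @export
simulate_spectral_counts <- function(n_proteins = 500,
                                     registry = default_effect_registry(),
                                     reps = 3, mean_count = 60,
                                     seed = 1) {
  stopifnot(n_proteins >= nrow(registry), mean_count > 0, reps >= 1)
  set.seed(seed)
  fc <- rep(1, n_proteins)
  nreg <- nrow(registry)
  ids <- c(registry$feature_id,
           sprintf("prot_%04d", seq_len(n_proteins - nreg)))
  fc[seq_len(nreg)] <- registry$protein_fc
  base <- stats::rgamma(n_proteins, shape = 2, rate = 2 / mean_count)
  # methanol dehydrogenases and their partners are abundant proteins;
  # anchor registry entries at or above the table average
  base[seq_len(nreg)] <- stats::runif(nreg, mean_count, 3 * mean_count)
  mu <- cbind(matrix(rep(base, reps), ncol = reps),
              matrix(rep(base * fc, reps), ncol = reps))
  counts <- matrix(0L, n_proteins, 2 * reps)
  for (j in seq_len(ncol(mu)))
    counts[, j] <- stats::rpois(n_proteins, mu[, j])
  condition <- rep(c("Ca", "La"), each = reps)
  colnames(counts) <- paste(condition, rep(seq_len(reps), 2), sep = "_")
  rownames(counts) <- ids
  list(counts = counts, condition = condition,
       truth = data.frame(feature_id = ids, fold_change = fc,
                          base_mean = base, stringsAsFactors = FALSE))
}

#' Simulate a metabolite abundance table
#'
#' Log-normal abundances: metabolites marked `down` get
#' `-effect_magnitude_log2` in the La condition, `up`
#' `+effect_magnitude_log2`, `flat` zero, plus Gaussian noise on the
#' log2 scale.
#'
#' @param pattern A [default_metabolite_pattern()]-shaped `data.frame`.
#' @param effect_magnitude_log2 Planted |log2| effect (default 1).
#' @param reps Replicates per condition (default 3).
#' @param noise_sd Replicate noise sd on the log2 scale (default 0.3).
#' @param seed Integer seed.
#' @return List with `abundances` (matrix), `condition` and `truth`.
#' @export
simulate_metabolites <- function(pattern = default_metabolite_pattern(),
                                 effect_magnitude_log2 = 1, reps = 3,
                                 noise_sd = 0.3, seed = 1) {
  stopifnot(noise_sd >= 0, reps >= 1, effect_magnitude_log2 >= 0,
            all(pattern$direction %in% c("down", "flat", "up")))
  set.seed(seed)
  n <- nrow(pattern)
  base_log2 <- stats::runif(n, 8, 14)
  shift <- effect_magnitude_log2 *
    (as.integer(pattern$direction == "up") -
       as.integer(pattern$direction == "down"))
  mu <- cbind(matrix(rep(base_log2, reps), ncol = reps),
              matrix(rep(base_log2 + shift, reps), ncol = reps))
  ab <- 2 ^ (mu + matrix(stats::rnorm(n * 2 * reps, 0, noise_sd),
                         nrow = n))
  condition <- rep(c("Ca", "La"), each = reps)
  colnames(ab) <- paste(condition, rep(seq_len(reps), 2), sep = "_")
  rownames(ab) <- pattern$metabolite
  list(abundances = ab, condition = condition,
       truth = data.frame(metabolite = pattern$metabolite,
                          direction = pattern$direction,
                          log2_effect = shift, stringsAsFactors = FALSE))
}

#' Simple differential-expression table from a count matrix
#'
#' A lightweight stand-in for a full count-model DE analysis, used to
#' close the loop between the synthetic counts and the DE decision
#' rules: per-feature log2 fold-change of (pseudocounted, depth-
#' normalized) condition means and a Welch t-test on log2-transformed
#' normalized counts.
#'
#' @param counts Count matrix (features x samples).
#' @param condition Condition label per column (two levels).
#' @param reference,case Condition labels (default `"Ca"`, `"La"`).
#' @return `data.frame` with `feature_id`, `log2fc`, `pvalue`.
#' @export
simple_de_table <- function(counts, condition, reference = "Ca",
                            case = "La") {
  x <- as.matrix(counts)
  stopifnot(length(condition) == ncol(x))
  # library-size normalization to the mean depth
  sf <- colSums(x) / mean(colSums(x))
  xn <- sweep(x, 2, sf, "/")
  lx <- log2(xn + 1)
  ref_cols <- condition == reference
  case_cols <- condition == case
  log2fc <- log2((rowMeans(xn[, case_cols, drop = FALSE]) + 1) /
                   (rowMeans(xn[, ref_cols, drop = FALSE]) + 1))
  pvalue <- apply(lx, 1, function(row) {
    a <- row[case_cols]; b <- row[ref_cols]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) return(1)
    tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
  })
  data.frame(feature_id = rownames(x), log2fc = log2fc, pvalue = pvalue,
             row.names = NULL, stringsAsFactors = FALSE)
}
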