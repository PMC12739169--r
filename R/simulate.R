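#' Simulate a subtype-structured expression cohort
#'
#' Generates a log2-scale genes-by-samples matrix with four molecular
#' subtypes (C1 mesenchymal, C2 immune-reactive, C4 differentiated, C5
#' proliferative/immune-evasive). Each subtype owns a disjoint block of
#' signature genes; in a sample of subtype k those genes are shifted up by
#' `effect_size` log2 units over a per-gene baseline, with Gaussian noise:
#'
#'   x_gs = baseline_g + effect_size * 1\[g in signature(subtype(s))\] + N(0, noise_sd)
#'
#' An 8-gene oncofetal RNA-binding-protein (RBP) signature is embedded as
#' the first genes of the C5 block (named after the canonical oncofetal
#' RBPs), so it is up-shifted in C5 samples only — the structure a
#' C5-vs-rest signature classifier assumes.
#'
#' @param n_per_subtype Named integer vector, samples per subtype.
#' @param n_genes Total genes; must cover all signature blocks.
#' @param signature_size Signature genes per subtype.
#' @param rbp_signature_size Size of the embedded RBP subset of the C5
#'   signature (default 8; capped at `signature_size`).
#' @param effect_size Log2 up-shift of signature genes in their own subtype.
#' @param noise_sd Gaussian noise sd in log2 units.
#' @param baseline_range Range of per-gene baseline means (log2 units).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @return A list with `matrix` (an [expr_matrix()], log2 scale), `labels`
#'   (tibble `sample_id`, `subtype`), and `signatures` (a [gene_sets()]
#'   collection: one set per subtype plus `RBP` for the embedded RBP subset).
#' @examples
#' sim <- simulate_subtype_cohort(n_per_subtype = c(C1 = 5, C5 = 5),
#'                                n_genes = 120, signature_size = 20, seed = 1)
#' sim$labels
#' @export
simulate_subtype_cohort <- function(n_per_subtype = c(C1 = 40, C2 = 40, C4 = 40, C5 = 40),
                                    n_genes = 1000,
                                    signature_size = 50,
                                    rbp_signature_size = 8,
                                    effect_size = 2,
                                    noise_sd = 1,
                                    baseline_range = c(3, 8),
                                    seed = NULL) {
  subtypes <- names(n_per_subtype)
  if (is.null(subtypes) || any(!nzchar(subtypes))) {
    abort("`n_per_subtype` must be a named vector of subtype sizes.")
  }
  if (any(n_per_subtype < 1L)) abort("each subtype needs at least 1 sample.")
  k <- length(subtypes)
  if (k * signature_size > n_genes) {
    abort(sprintf("gene budget exceeded: %d subtypes x %d signature genes > %d genes",
                  k, signature_size, n_genes))
  }
  if (noise_sd <= 0) abort("`noise_sd` must be > 0.")
  if (effect_size < 0) abort("`effect_size` must be >= 0.")
  rbp_signature_size <- min(rbp_signature_size, signature_size)

  genes <- sprintf("G%04d", seq_len(n_genes))
  rbp_symbols <- c("DDX25", "ELAVL3", "IGF2BP1", "IGF2BP3",
                   "LIN28B", "MEX3A", "MKRN3", "MSI1")
  # The RBP subset heads the C5 block and takes the canonical symbols (up to 8).
  if ("C5" %in% subtypes && rbp_signature_size > 0L) {
    c5_start <- (match("C5", subtypes) - 1L) * signature_size + 1L
    nsym <- min(rbp_signature_size, length(rbp_symbols))
    genes[c5_start + seq_len(nsym) - 1L] <- rbp_symbols[seq_len(nsym)]
    if (rbp_signature_size > nsym) {
      extra <- c5_start + nsym:(rbp_signature_size - 1L)
      genes[extra] <- paste0("RBPX", seq_along(extra))
    }
  }

  sig_list <- lapply(seq_len(k), function(i) {
    genes[((i - 1L) * signature_size + 1L):(i * signature_size)]
  })
  names(sig_list) <- subtypes
  if ("C5" %in% subtypes && rbp_signature_size > 0L) {
    sig_list$RBP <- sig_list$C5[seq_len(rbp_signature_size)]
  }

  labels <- tibble(
    sample_id = sprintf("S%04d", seq_len(sum(n_per_subtype))),
    subtype = rep(subtypes, times = n_per_subtype)
  )

  gen <- function() {
    baseline <- runif(n_genes, baseline_range[1L], baseline_range[2L])
    vals <- matrix(rnorm(n_genes * nrow(labels), sd = noise_sd),
                   nrow = n_genes) + baseline
    for (i in seq_len(k)) {
      cols <- which(labels$subtype == subtypes[i])
      rows <- ((i - 1L) * signature_size + 1L):(i * signature_size)
      vals[rows, cols] <- vals[rows, cols] + effect_size
    }
    vals
  }
  vals <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  dimnames(vals) <- list(genes, labels$sample_id)

  list(
    matrix = expr_matrix(vals, scale = "log2"),
    labels = labels,
    signatures = gene_sets(sig_list,
                           descriptions = rep("synthetic ground-truth signature",
                                              length(sig_list)))
  )
}

#' Simulate 4PL dose-response viability data
#'
#' Draws viability observations from four-parameter logistic curves
#' `v(c) = bottom + (top - bottom) / (1 + (c / ec50)^hill)` at a geometric
#' concentration series, adds Gaussian noise and truncates at 0. The default
#' curve set emulates a checkpoint-inhibitor combination experiment: an
#' antibody titration alone and again in the presence of a fixed dose of a
#' small-molecule partner that potentiates it ~17-fold, plus the partner's
#' own monotherapy titration.
#'
#' @param curves Tibble with one row per (drug, arm): columns `drug`, `arm`
#'   ("mono"/"combo"), `top`, `bottom`, `ec50`, `hill`, `conc_min`,
#'   `conc_max`, `n_conc`, `conc_unit`.
#' @param noise_sd Gaussian noise sd on the viability fraction.
#' @param replicates Replicates per concentration.
#' @param seed Integer seed.
#' @return A dose-response tibble (see [read_dose_response()]).
#' @examples
#' simulate_dose_response(noise_sd = 0, replicates = 1, seed = 1)
#' @export
simulate_dose_response <- function(curves = default_synergy_curves(),
                                   noise_sd = 0.02,
                                   replicates = 3,
                                   seed = NULL) {
  curves <- as_tibble(curves)
  need <- c("drug", "arm", "top", "bottom", "ec50", "hill",
            "conc_min", "conc_max", "n_conc", "conc_unit")
  if (!all(need %in% names(curves))) {
    abort(paste0("`curves` needs columns: ", paste(need, collapse = ", ")))
  }
  if (any(curves$bottom >= curves$top)) abort("each curve needs bottom < top.")
  if (any(curves$n_conc < 4L)) abort("each curve needs >= 4 concentrations.")
  if (any(curves$ec50 <= 0 | curves$hill <= 0)) abort("ec50 and hill must be > 0.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")

  gen <- function() {
    purrr::pmap(curves, function(drug, arm, top, bottom, ec50, hill,
                                 conc_min, conc_max, n_conc, conc_unit, ...) {
      conc <- 10^seq(log10(conc_min), log10(conc_max), length.out = n_conc)
      grid <- tidyr::expand_grid(concentration = conc,
                                 replicate = seq_len(replicates))
      v <- four_pl(grid$concentration, top, bottom, ec50, hill)
      if (noise_sd > 0) v <- v + rnorm(nrow(grid), sd = noise_sd)
      tibble(drug = drug, arm = arm,
             concentration = grid$concentration, conc_unit = conc_unit,
             viability = pmax(v, 0), replicate = grid$replicate)
    }) |> purrr::list_rbind()
  }
  out <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  validate_dose_response(out)
}

#' Default synergy simulation curves
#'
#' Default parameters of the combination experiment: antibody monotherapy
#' EC50 87.7 ng/mL, antibody EC50 under the fixed-dose combination
#' 5.3 ng/mL (~17-fold potentiation), partner-compound monotherapy EC50
#' 8.6 uM; fixed combination partner dose 5 uM (0.58 of its own EC50).
#'
#' @return A tibble of curve parameters for [simulate_dose_response()].
#' @export
default_synergy_curves <- function() {
  tibble(
    drug = c("antibody", "antibody", "partner"),
    arm = c("mono", "combo", "mono"),
    top = 1, bottom = 0.05,
    ec50 = c(87.7, 5.3, 8.6),
    hill = 1,
    conc_min = c(0.1, 0.1, 0.05),
    conc_max = c(10000, 10000, 100),
    n_conc = 8L,
    conc_unit = c("ng/mL", "ng/mL", "uM")
  )
}

#' Simulate a clustered cell population with negative-binomial counts
#'
#' Emulates the structure behind per-cluster immune-marker read summaries:
#' cells belong to named clusters, each cluster has its own per-gene mean
#' profile, and counts are drawn negative-binomially (shared dispersion)
#' around the cluster means rescaled to a common library size.
#'
#' @param clusters Tibble with columns `cluster` (unique names) and
#'   `n_cells` (>= 1).
#' @param gene_means Genes x clusters numeric matrix of nonnegative mean
#'   expression (rownames = genes, colnames = cluster names). Relative
#'   values per column are rescaled to `library_size`.
#' @param library_size Expected total counts per cell.
#' @param dispersion Negative-binomial size parameter (larger = closer to
#'   Poisson).
#' @param seed Integer seed.
#' @return A list with `matrix` (an [expr_matrix()], linear counts) and
#'   `labels` (tibble `cell_id`, `cluster`).
#' @seealso [cell_population_means()] for a marker-ratio mean builder.
#' @export
simulate_cell_population <- function(clusters, gene_means,
                                     library_size = 5000,
                                     dispersion = 2,
                                     seed = NULL) {
  clusters <- as_tibble(clusters)
  if (!all(c("cluster", "n_cells") %in% names(clusters))) {
    abort("`clusters` needs columns cluster and n_cells.")
  }
  if (anyDuplicated(clusters$cluster)) abort("cluster names must be unique.")
  if (any(clusters$n_cells < 1L)) abort("each cluster needs >= 1 cell.")
  if (!is.matrix(gene_means) || is.null(rownames(gene_means)) ||
      is.null(colnames(gene_means))) {
    abort("`gene_means` must be a named genes x clusters matrix.")
  }
  if (!all(clusters$cluster %in% colnames(gene_means))) {
    abort("every cluster needs a column in `gene_means`.")
  }
  if (any(gene_means < 0)) abort("gene means must be >= 0.")
  if (library_size <= 0 || dispersion <= 0) {
    abort("`library_size` and `dispersion` must be > 0.")
  }
  zero_col <- colSums(gene_means[, clusters$cluster, drop = FALSE]) == 0
  if (any(zero_col)) abort("a cluster mean profile is all zero.")

  n_genes <- nrow(gene_means)
  labels <- tibble(
    cell_id = sprintf("cell%05d", seq_len(sum(clusters$n_cells))),
    cluster = rep(clusters$cluster, times = clusters$n_cells)
  )
  gen <- function() {
    counts <- matrix(0L, nrow = n_genes, ncol = nrow(labels))
    for (cl in clusters$cluster) {
      mu <- gene_means[, cl] / sum(gene_means[, cl]) * library_size
      cols <- which(labels$cluster == cl)
      counts[, cols] <- rnbinom(n_genes * length(cols), mu = mu, size = dispersion)
    }
    counts
  }
  counts <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  dimnames(counts) <- list(rownames(gene_means), labels$cell_id)
  list(matrix = expr_matrix(counts + 0, scale = "linear"), labels = labels)
}

#' Build cluster mean profiles around an MHC-I/PD-L1 ratio directive
#'
#' Convenience constructor for [simulate_cell_population()]: a background of
#' equal-mean genes plus the class-I HLA panel (HLA-A/B/C) and PD-L1
#' (CD274), with the summed MHC-I mean set to `mhc_pdl1_ratio` times the
#' PD-L1 mean in each cluster.
#'
#' @param cluster_names Character vector of cluster names.
#' @param mhc_pdl1_ratio Numeric vector (recycled) of target ratios of
#'   cumulative MHC-I mean to PD-L1 mean per cluster.
#' @param n_background_genes Number of background genes.
#' @param marker_mean Mean assigned to PD-L1 (MHC-I genes share
#'   `marker_mean * ratio / 3` each); background genes get mean 1.
#' @return A genes x clusters mean matrix.
#' @export
cell_population_means <- function(cluster_names,
                                  mhc_pdl1_ratio = 1,
                                  n_background_genes = 200,
                                  marker_mean = 20) {
  ratio <- rep_len(mhc_pdl1_ratio, length(cluster_names))
  genes <- c("HLA-A", "HLA-B", "HLA-C", "CD274",
             sprintf("BG%04d", seq_len(n_background_genes)))
  m <- matrix(1, nrow = length(genes), ncol = length(cluster_names),
              dimnames = list(genes, cluster_names))
  for (j in seq_along(cluster_names)) {
    m["CD274", j] <- marker_mean
    m[c("HLA-A", "HLA-B", "HLA-C"), j] <- marker_mean * ratio[j] / 3
  }
  m
}

# 4PL response: top at c -> 0, bottom at c -> Inf (hill > 0).
four_pl <- function(conc, top, bottom, ec50, hill) {
  bottom + (top - bottom) / (1 + (conc / ec50)^hill)
}
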