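# Synthetic scRNA-seq generator: Poisson counts over per-gene log-normal
# rates, two gene classes (silent / expressed), per-cell sequencing depth,
# cluster structure as log-scale mean shifts, and optional planted
# suppressed-gene sets in a focal component.

#' Simulation configuration for the synthetic scRNA-seq generator
#'
#' Describes a single-condition single-cell experiment: a gene universe split
#' into a silent and an expressed class, a set of cell components (clusters)
#' given as sizes, log-scale mean shifts and optional planted suppressed-gene
#' counts, plus a tail of low-depth cells destined to fail quality control.
#'
#' Gene-level draws (class membership, lengths, per-gene mean expression) are
#' controlled by `gene_seed`, cell-level draws by `seed`. Two configurations
#' sharing `gene_seed`, `n_genes` and the gene-class parameters therefore
#' share the same gene universe, so datasets generated for different
#' conditions can be analysed jointly gene-by-gene.
#'
#' Expressed-gene mean RPKM levels are rescaled at generation time so that
#' the expected total count of an unshifted cell equals its drawn sequencing
#' depth (sum of mean RPKM times length in kb equals 1e6).
#'
#' @param n_genes Number of genes in the universe.
#' @param silent_gene_fraction Fraction of genes in the silent class.
#' @param gene_length_meanlog,gene_length_sdlog Log-normal parameters of
#'   gene lengths in kb (median 2 kb by default).
#' @param expressed_mu Across-gene log-scale centre of expressed-gene mean
#'   RPKM before depth normalisation.
#' @param expressed_mu_sd Across-gene log-scale spread of expressed-gene
#'   mean RPKM.
#' @param expressed_sigma Within-gene, across-cell log-scale biological
#'   noise of expressed genes.
#' @param silent_mu,silent_sigma Log-normal parameters of the (low) RPKM
#'   level a silent gene takes in the rare cells where it fires.
#' @param prevalence_dropout Probability that a silent gene is exactly zero
#'   in a given cell.
#' @param cluster_spec List of components, each a list with `n_cells`,
#'   `mean_shift` (log-scale offset added to the program genes of the
#'   component's cells) and `suppressed_gene_count` (genes planted as fully
#'   suppressed in this component's cells).
#' @param program_gene_fraction Fraction of expressed genes belonging to the
#'   shared expression program that component mean shifts act on. A shift on
#'   a strict subset survives the per-cell total normalisation built into
#'   RPKM (a shift of the whole transcriptome would cancel out of it), and a
#'   single shared program keeps all component centroids on one line in
#'   expression space.
#' @param suppressed_min_rpkm Minimum depth-normalised mean RPKM a gene must
#'   have to be eligible for planting as suppressed (keeps planted genes
#'   clearly expressed in all other components).
#' @param n_low_depth_cells Number of additional cells emitted with total
#'   counts below one million (drawn from the largest component).
#' @param low_depth_range Range, in units of 1e6 reads, of the sequencing
#'   depth of low-depth cells.
#' @param total_reads_mean Expected per-cell sequencing depth of regular
#'   cells.
#' @param depth_sdlog Log-scale spread of per-cell depth.
#' @param condition Condition tag attached to every emitted cell.
#' @param seed Integer seed for cell-level randomness.
#' @param gene_seed Integer seed for gene-level randomness (shared across
#'   conditions by default).
#' @return An object of class `sc_sim_config` (a validated list).
#' @seealso [baseline_preset()], [metformin_preset()], [generate_dataset()]
#' @export
sim_config <- function(n_genes = 23398L,
                       silent_gene_fraction = 0.80,
                       gene_length_meanlog = log(2),
                       gene_length_sdlog = 0.6,
                       expressed_mu = log(90),
                       expressed_mu_sd = 0.4,
                       expressed_sigma = 0.03,
                       silent_mu = log(0.5),
                       silent_sigma = 1,
                       prevalence_dropout = 0.95,
                       program_gene_fraction = 0.3,
                       cluster_spec = list(list(n_cells = 100L,
                                                mean_shift = 0,
                                                suppressed_gene_count = 0L)),
                       suppressed_min_rpkm = 40,
                       n_low_depth_cells = 0L,
                       low_depth_range = c(0.2, 0.9),
                       total_reads_mean = 3.0e6,
                       depth_sdlog = 0.25,
                       condition = "baseline",
                       seed = 1L,
                       gene_seed = 104729L) {
  cfg <- list(n_genes = as.integer(n_genes),
              silent_gene_fraction = silent_gene_fraction,
              gene_length_meanlog = gene_length_meanlog,
              gene_length_sdlog = gene_length_sdlog,
              expressed_mu = expressed_mu,
              expressed_mu_sd = expressed_mu_sd,
              expressed_sigma = expressed_sigma,
              silent_mu = silent_mu,
              silent_sigma = silent_sigma,
              prevalence_dropout = prevalence_dropout,
              program_gene_fraction = program_gene_fraction,
              cluster_spec = cluster_spec,
              suppressed_min_rpkm = suppressed_min_rpkm,
              n_low_depth_cells = as.integer(n_low_depth_cells),
              low_depth_range = low_depth_range,
              total_reads_mean = total_reads_mean,
              depth_sdlog = depth_sdlog,
              condition = condition,
              seed = as.integer(seed),
              gene_seed = as.integer(gene_seed))
  class(cfg) <- "sc_sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg An `sc_sim_config` object.
#' @return The configuration, invisibly, if valid; otherwise an error.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sc_sim_config"))
  if (cfg$n_genes < 2L) {
    stop("configuration error: 'n_genes' must be at least 2", call. = FALSE)
  }
  fr <- cfg$silent_gene_fraction
  if (!is.numeric(fr) || fr < 0 || fr > 1) {
    stop("configuration error: 'silent_gene_fraction' must lie in [0, 1]",
         call. = FALSE)
  }
  if (cfg$prevalence_dropout < 0 || cfg$prevalence_dropout > 1) {
    stop("configuration error: 'prevalence_dropout' must lie in [0, 1]",
         call. = FALSE)
  }
  if (!length(cfg$cluster_spec)) {
    stop("configuration error: 'cluster_spec' must list at least one component",
         call. = FALSE)
  }
  n_expressed <- cfg$n_genes - round(cfg$n_genes * fr)
  for (comp in cfg$cluster_spec) {
    if (!all(c("n_cells", "mean_shift", "suppressed_gene_count") %in%
               names(comp))) {
      stop("configuration error: each component needs n_cells, mean_shift, ",
           "suppressed_gene_count", call. = FALSE)
    }
    if (comp$n_cells < 1) {
      stop("configuration error: component sizes must be positive",
           call. = FALSE)
    }
    if (comp$suppressed_gene_count < 0 ||
        comp$suppressed_gene_count > n_expressed) {
      stop("configuration error: suppressed_gene_count must lie between 0 ",
           "and the number of expressed genes (", n_expressed, ")",
           call. = FALSE)
    }
  }
  if (cfg$n_low_depth_cells < 0) {
    stop("configuration error: 'n_low_depth_cells' must be non-negative",
         call. = FALSE)
  }
  if (cfg$total_reads_mean <= 0) {
    stop("configuration error: 'total_reads_mean' must be positive",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sc_sim_config <- function(x, ...) {
  sizes <- vapply(x$cluster_spec, function(co) co$n_cells, numeric(1))
  sup <- vapply(x$cluster_spec, function(co) co$suppressed_gene_count,
                numeric(1))
  cat("Synthetic scRNA-seq configuration (", x$condition, ")\n", sep = "")
  cat("  genes: ", x$n_genes, " (silent fraction ",
      format(x$silent_gene_fraction), ")\n", sep = "")
  cat("  components: ", paste(sizes, collapse = ", "),
      " cells; suppressed genes: ", paste(sup, collapse = ", "), "\n",
      sep = "")
  cat("  low-depth cells: ", x$n_low_depth_cells,
      "; mean depth: ", format(x$total_reads_mean, big.mark = ","),
      "; seed: ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Preset emulating the untreated (baseline) condition
#'
#' Two components of 158 and 20 cells separated by a moderate log-scale mean
#' shift, no planted suppression, plus 20 low-depth cells that fail the
#' one-million-read quality cut.
#'
#' @param seed Cell-level seed.
#' @param n_genes Gene universe size (reduce for quick experiments; gene
#'   class proportions and planted structure scale with it).
#' @return An `sc_sim_config`.
#' @export
baseline_preset <- function(seed = 1L, n_genes = 23398L) {
  sim_config(n_genes = n_genes,
             cluster_spec = list(
               list(n_cells = 158L, mean_shift = 0,
                    suppressed_gene_count = 0L),
               list(n_cells = 20L, mean_shift = 1.7,
                    suppressed_gene_count = 0L)),
             n_low_depth_cells = 20L,
             condition = "baseline",
             seed = seed)
}

#' Preset emulating the drug-treated condition
#'
#' Three components of 160, 6 and 12 cells. The 6-cell minority component
#' carries 230 planted fully suppressed genes; the 12-cell component carries
#' a distinct mean shift. 18 additional low-depth cells fail quality control.
#'
#' @inheritParams baseline_preset
#' @return An `sc_sim_config`.
#' @export
metformin_preset <- function(seed = 2L, n_genes = 23398L) {
  sim_config(n_genes = n_genes,
             cluster_spec = list(
               list(n_cells = 160L, mean_shift = 0.15,
                    suppressed_gene_count = 0L),
               list(n_cells = 6L, mean_shift = 0.15,
                    suppressed_gene_count = 230L),
               list(n_cells = 12L, mean_shift = 1.7,
                    suppressed_gene_count = 0L)),
             n_low_depth_cells = 18L,
             condition = "metformin",
             seed = seed)
}

#' Evaluate an expression with a private RNG stream
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state,
#' so seeded package operations never disturb the session's stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Gene-level universe shared across conditions: class membership, lengths,
# depth-normalised expressed-gene mean RPKM.
draw_gene_universe <- function(cfg) {
  with_local_seed(cfg$gene_seed, {
    G <- cfg$n_genes
    gene_ids <- sprintf("G%05d", seq_len(G))
    n_silent <- round(G * cfg$silent_gene_fraction)
    silent <- logical(G)
    silent[sample.int(G, n_silent)] <- TRUE
    lengths_kb <- stats::rlnorm(G, cfg$gene_length_meanlog,
                                cfg$gene_length_sdlog)
    mean_rpkm <- numeric(G)
    n_expr <- G - n_silent
    if (n_expr > 0L) {
      m <- exp(stats::rnorm(n_expr, cfg$expressed_mu, cfg$expressed_mu_sd))
      # depth normalisation: an unshifted cell's expected total count equals
      # its sequencing depth (sum of RPKM * length_kb = 1e6)
      m <- m * 1e6 / sum(m * lengths_kb[!silent])
      mean_rpkm[!silent] <- m
    }
    # shared expression program: the expressed-gene subset that component
    # mean shifts act on (identical across conditions via gene_seed)
    program <- logical(G)
    expr_pos <- which(!silent)
    n_prog <- round(length(expr_pos) * cfg$program_gene_fraction)
    if (n_prog > 0L) program[sample(expr_pos, n_prog)] <- TRUE
    list(gene_ids = gene_ids, silent = silent, lengths_kb = lengths_kb,
         mean_rpkm = mean_rpkm, program = program)
  })
}

#' Generate a synthetic scRNA-seq dataset
#'
#' Draws per-cell sequencing depths, per-gene-and-cell true RPKM levels
#' (log-normal noise around class means, log-scale component shifts,
#' Bernoulli dropout for silent genes), converts them to Poisson counts at
#' the drawn depth, zeroes planted suppressed genes in their component's
#' cells, and derives the RPKM matrix from the realised counts. Fully
#' deterministic given the configuration.
#'
#' @param cfg An `sc_sim_config`.
#' @return An object of class `sc_dataset`: a list with `counts` and `rpkm`
#'   (gene-by-cell matrices), `gene_lengths_kb`, `totals` (per-cell total
#'   counts), `true_labels` (component index per cell), `is_low_depth`,
#'   `condition` (per-cell tag), `suppressed_genes` (per-component character
#'   vectors of planted gene ids) and the `config`.
#' @export
generate_dataset <- function(cfg) {
  validate_sim_config(cfg)
  uni <- draw_gene_universe(cfg)
  G <- cfg$n_genes
  sizes <- vapply(cfg$cluster_spec, function(co) as.integer(co$n_cells),
                  integer(1))
  shifts <- vapply(cfg$cluster_spec, function(co) co$mean_shift, numeric(1))
  n_comp_cells <- sum(sizes)
  n_low <- cfg$n_low_depth_cells
  N <- n_comp_cells + n_low
  majority <- which.max(sizes)

  with_local_seed(cfg$seed, {
    comp <- c(rep.int(seq_along(sizes), sizes), rep.int(majority, n_low))
    is_low <- c(rep(FALSE, n_comp_cells), rep(TRUE, n_low))
    depth <- stats::rlnorm(N, log(cfg$total_reads_mean) -
                             cfg$depth_sdlog^2 / 2, cfg$depth_sdlog)
    if (n_low > 0L) {
      depth[is_low] <- stats::runif(n_low, cfg$low_depth_range[1],
                                    cfg$low_depth_range[2]) * 1e6
    }

    # planted suppressed genes, per component, among genes that stay well
    # expressed in *every* component. A component's shift inflates its
    # cells' totals by T_k = 1 + phi * (e^s - 1) (phi = program mass
    # share), which divides every RPKM in that component by T_k; the
    # eligibility bound uses each gene's worst-case renormalised mean.
    phi_mass <- sum(uni$mean_rpkm[uni$program] *
                      uni$lengths_kb[uni$program]) / 1e6
    t_k <- 1 + phi_mass * (exp(shifts) - 1)
    worst_prog <- min(exp(shifts) / t_k)
    worst_nonprog <- min(1 / t_k)
    worst_factor <- ifelse(uni$program, worst_prog, worst_nonprog)
    eligible <- which(!uni$silent &
                        uni$mean_rpkm * worst_factor >
                          cfg$suppressed_min_rpkm)
    suppressed <- vector("list", length(sizes))
    for (k in seq_along(sizes)) {
      cnt <- as.integer(cfg$cluster_spec[[k]]$suppressed_gene_count)
      if (cnt > 0L) {
        if (cnt > length(eligible)) {
          stop("configuration error: not enough well-expressed genes to ",
               "plant ", cnt, " suppressed genes", call. = FALSE)
        }
        suppressed[[k]] <- sort(uni$gene_ids[sample(eligible, cnt)])
      } else {
        suppressed[[k]] <- character(0)
      }
    }

    # true per-gene, per-cell RPKM levels
    lam <- matrix(0, nrow = G, ncol = N)
    expr_idx <- which(!uni$silent)
    if (length(expr_idx)) {
      noise <- matrix(stats::rnorm(length(expr_idx) * N, 0,
                                   cfg$expressed_sigma),
                      nrow = length(expr_idx))
      lam[expr_idx, ] <- uni$mean_rpkm[expr_idx] * exp(noise)
      # component shifts act on the shared program genes only; a shift on
      # the whole transcriptome would cancel out of RPKM
      shift_factor <- exp(outer(as.numeric(uni$program[expr_idx]),
                                shifts[comp]))
      lam[expr_idx, ] <- lam[expr_idx, , drop = FALSE] * shift_factor
    }
    sil_idx <- which(uni$silent)
    if (length(sil_idx)) {
      nsil <- length(sil_idx) * N
      fire <- stats::runif(nsil) >= cfg$prevalence_dropout
      level <- exp(stats::rnorm(nsil, cfg$silent_mu, cfg$silent_sigma))
      lam[sil_idx, ] <- matrix(ifelse(fire, level, 0),
                               nrow = length(sil_idx))
    }
    for (k in seq_along(sizes)) {
      if (length(suppressed[[k]])) {
        lam[match(suppressed[[k]], uni$gene_ids), comp == k] <- 0
      }
    }

    rate <- lam * uni$lengths_kb
    rate <- sweep(rate, 2, depth / 1e6, "*")
    counts <- matrix(stats::rpois(G * N, rate), nrow = G, ncol = N)

    perm <- sample.int(N)
    counts <- counts[, perm, drop = FALSE]
    comp <- comp[perm]
    is_low <- is_low[perm]

    tag <- toupper(substr(cfg$condition, 1, 1))
    cell_ids <- sprintf("%s%03d", tag, seq_len(N))
    dimnames(counts) <- list(uni$gene_ids, cell_ids)
    totals <- colSums(counts)
    rpkm <- rpkm_from_counts(counts, uni$lengths_kb, totals)

    structure(list(counts = counts,
                   rpkm = rpkm,
                   gene_lengths_kb = stats::setNames(uni$lengths_kb,
                                                     uni$gene_ids),
                   totals = totals,
                   true_labels = stats::setNames(comp, cell_ids),
                   is_low_depth = stats::setNames(is_low, cell_ids),
                   condition = stats::setNames(rep(cfg$condition, N),
                                               cell_ids),
                   suppressed_genes = suppressed,
                   program_genes = uni$gene_ids[uni$program],
                   config = cfg),
              class = "sc_dataset")
  })
}

#' @export
print.sc_dataset <- function(x, ...) {
  cat("Synthetic scRNA-seq dataset (", x$config$condition, "): ",
      nrow(x$counts), " genes x ", ncol(x$counts), " cells\n", sep = "")
  tab <- table(x$true_labels[!x$is_low_depth])
  cat("  component sizes: ", paste(tab, collapse = ", "),
      "; low-depth cells: ", sum(x$is_low_depth), "\n", sep = "")
  nsup <- vapply(x$suppressed_genes, length, integer(1))
  if (any(nsup > 0)) {
    cat("  planted suppressed genes per component: ",
        paste(nsup, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Convert a count matrix to RPKM
#'
#' RPKM(g, c) = counts(g, c) / (length_kb(g) * totals(c) / 1e6), i.e. reads
#' per kilobase of transcript per million mapped reads.
#'
#' @param counts Non-negative gene-by-cell count matrix.
#' @param gene_lengths_kb Per-gene transcript lengths in kilobases.
#' @param totals Per-cell total mapped reads; defaults to the column sums of
#'   `counts`.
#' @return A gene-by-cell RPKM matrix with the dimnames of `counts`.
#' @export
rpkm_from_counts <- function(counts, gene_lengths_kb, totals = NULL) {
  if (!is.matrix(counts) || any(counts < 0)) {
    stop("'counts' must be a non-negative matrix", call. = FALSE)
  }
  if (length(gene_lengths_kb) != nrow(counts)) {
    stop("'gene_lengths_kb' must have one entry per gene", call. = FALSE)
  }
  if (any(gene_lengths_kb <= 0)) {
    stop("gene lengths must be positive", call. = FALSE)
  }
  if (is.null(totals)) totals <- colSums(counts)
  if (length(totals) != ncol(counts)) {
    stop("'totals' must have one entry per cell", call. = FALSE)
  }
  if (any(totals <= 0)) {
    bad <- which(totals <= 0)
    nm <- if (!is.null(colnames(counts))) colnames(counts)[bad] else bad
    stop("cell(s) with zero total counts: ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  r <- counts / gene_lengths_kb
  r <- sweep(r, 2, totals / 1e6, "/")
  dimnames(r) <- dimnames(counts)
  r
}
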