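#' Simulation configuration
#'
#' Parameters of the multi-batch negative-binomial atlas generator. The
#' generative model: each cell type has a baseline log-mean expression
#' vector with a disjoint block of elevated marker genes; each subtype adds
#' Normal(0, subtype_shift_sd) log-offsets on a random gene subset; each
#' batch multiplies gene means by exp(Normal(0, batch_effect_sd)); each cell
#' draws a log-normal library size; counts are negative binomial with a
#' gene-shared dispersion. Reference batches omit query-only types and vice
#' versa, creating the partial-overlap (interfering cell type) topology.
#'
#' @param n_types_shared,n_types_ref_only,n_types_query_only type counts per
#'   overlap status; shared + ref_only must be >= 1.
#' @param subtypes_per_type subtypes per type (> 1 creates the
#'   resolution-mismatch scenario: reference labels are subtype-level,
#'   query truth records both levels).
#' @param n_genes total genes.
#' @param n_marker_genes_per_type disjoint marker-block size per type.
#' @param cells_per_type_per_batch cells per (type, batch) pair, split
#'   evenly over subtypes.
#' @param n_ref_batches,n_query_batches batch counts per domain.
#' @param batch_effect_sd log-scale SD of multiplicative per-batch gene
#'   effects (0 disables batch effects).
#' @param subtype_shift_sd log-scale SD of subtype offsets.
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param marker_logfc log-scale elevation of marker genes (default 2,
#'   about 7.4-fold).
#' @param baseline_logmean_sd SD of baseline gene log-means (default 0.4;
#'   larger values spread gene expression over more orders of magnitude, as
#'   in real atlases where stable housekeeping genes share the top
#'   expression range with markers).
#' @param libsize_meanlog,libsize_sdlog log-normal library-size parameters.
#' @param seed integer seed; same seed, same dataset, bitwise.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_types_shared = 5L, n_types_ref_only = 1L,
                       n_types_query_only = 1L, subtypes_per_type = 1L,
                       n_genes = 500L, n_marker_genes_per_type = 20L,
                       cells_per_type_per_batch = 250L,
                       n_ref_batches = 2L, n_query_batches = 2L,
                       batch_effect_sd = 0.3, subtype_shift_sd = 0.5,
                       dispersion = 0.15, marker_logfc = 2.0,
                       baseline_logmean_sd = 0.4,
                       libsize_meanlog = log(2500), libsize_sdlog = 0.35,
                       seed = 1L) {
  cfg <- list(n_types_shared = as.integer(n_types_shared),
              n_types_ref_only = as.integer(n_types_ref_only),
              n_types_query_only = as.integer(n_types_query_only),
              subtypes_per_type = as.integer(subtypes_per_type),
              n_genes = as.integer(n_genes),
              n_marker_genes_per_type = as.integer(n_marker_genes_per_type),
              cells_per_type_per_batch = as.integer(cells_per_type_per_batch),
              n_ref_batches = as.integer(n_ref_batches),
              n_query_batches = as.integer(n_query_batches),
              batch_effect_sd = batch_effect_sd,
              subtype_shift_sd = subtype_shift_sd,
              dispersion = dispersion, marker_logfc = marker_logfc,
              baseline_logmean_sd = baseline_logmean_sd,
              libsize_meanlog = libsize_meanlog, libsize_sdlog = libsize_sdlog,
              seed = as.integer(seed))
  if (cfg$n_types_shared + cfg$n_types_ref_only < 1L) {
    stop("sim_config: reference needs at least one type (shared + ref_only >= 1)")
  }
  if (cfg$n_genes < 1L || cfg$cells_per_type_per_batch < 1L) {
    stop("sim_config: need at least one gene and one cell per type per batch")
  }
  n_types <- cfg$n_types_shared + cfg$n_types_ref_only + cfg$n_types_query_only
  if (n_types * cfg$n_marker_genes_per_type > cfg$n_genes) {
    stop("sim_config: marker blocks exceed the gene count")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a partially overlapping multi-batch atlas
#'
#' Draws reference and query count matrices plus ground-truth tables from
#' the generative model described in \code{\link{sim_config}}. The query
#' matrix never carries a label field (truth is stored separately, so
#' leakage into the model input is impossible by construction).
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{ref} and \code{query}
#'   (\code{\link{annotated_matrix}}; only \code{ref} is labeled) and
#'   \code{truth}: \code{query_truth} (cell_id, type, subtype, batch,
#'   status), \code{ref_truth} (same columns for reference cells),
#'   \code{type_status} (type, status), \code{markers} (gene, type).
#' @export
simulate_atlas <- function(cfg) {
  set.seed(cfg$seed)
  types <- c(
    if (cfg$n_types_shared) paste0("shared_", seq_len(cfg$n_types_shared)),
    if (cfg$n_types_ref_only) paste0("refonly_", seq_len(cfg$n_types_ref_only)),
    if (cfg$n_types_query_only) paste0("queryonly_", seq_len(cfg$n_types_query_only))
  )
  status <- rep(c("shared", "ref_only", "query_only"),
                c(cfg$n_types_shared, cfg$n_types_ref_only, cfg$n_types_query_only))
  names(status) <- types
  genes <- sprintf("gene_%04d", seq_len(cfg$n_genes))
  base_log <- stats::rnorm(cfg$n_genes, 0, cfg$baseline_logmean_sd)

  nm <- cfg$n_marker_genes_per_type
  marker_idx <- lapply(seq_along(types), function(t) ((t - 1L) * nm + 1L):(t * nm))
  names(marker_idx) <- types
  type_log <- lapply(types, function(t) {
    mu <- base_log
    mu[marker_idx[[t]]] <- mu[marker_idx[[t]]] + cfg$marker_logfc
    mu
  })
  names(type_log) <- types

  ns <- cfg$subtypes_per_type
  sub_names <- lapply(types, function(t)
    if (ns > 1L) paste0(t, ".s", seq_len(ns)) else t)
  names(sub_names) <- types
  sub_log <- list()
  for (t in types) {
    for (s in seq_len(ns)) {
      off <- numeric(cfg$n_genes)
      if (ns > 1L && cfg$subtype_shift_sd > 0) {
        hit <- sample.int(cfg$n_genes, nm)
        off[hit] <- stats::rnorm(nm, 0, cfg$subtype_shift_sd)
      }
      sub_log[[sub_names[[t]][s]]] <- type_log[[t]] + off
    }
  }

  batches <- c(paste0("ref_b", seq_len(cfg$n_ref_batches)),
               paste0("query_b", seq_len(cfg$n_query_batches)))
  batch_eff <- lapply(batches, function(b)
    if (cfg$batch_effect_sd > 0) stats::rnorm(cfg$n_genes, 0, cfg$batch_effect_sd)
    else numeric(cfg$n_genes))
  names(batch_eff) <- batches

  gen_domain <- function(domain) {
    dom_batches <- if (domain == "ref") {
      paste0("ref_b", seq_len(cfg$n_ref_batches))
    } else {
      paste0("query_b", seq_len(cfg$n_query_batches))
    }
    dom_types <- types[status %in% c("shared",
                                     if (domain == "ref") "ref_only" else "query_only")]
    per_sub <- max(1L, cfg$cells_per_type_per_batch %/% ns)
    blocks <- list(); meta <- list()
    for (b in dom_batches) {
      for (t in dom_types) {
        for (s in seq_len(ns)) {
          sname <- sub_names[[t]][s]
          mu_log <- sub_log[[sname]] + batch_eff[[b]]
          lam <- exp(mu_log)
          prob <- lam / sum(lam)
          libs <- stats::rlnorm(per_sub, cfg$libsize_meanlog, cfg$libsize_sdlog)
          mu_mat <- outer(libs, prob)
          counts <- if (cfg$dispersion > 0) {
            matrix(stats::rnbinom(length(mu_mat), mu = as.vector(mu_mat),
                                  size = 1 / cfg$dispersion),
                   nrow = per_sub)
          } else {
            matrix(stats::rpois(length(mu_mat), as.vector(mu_mat)), nrow = per_sub)
          }
          blocks[[length(blocks) + 1L]] <- counts
          meta[[length(meta) + 1L]] <- data.frame(
            type = t, subtype = sname, batch = b, n = per_sub,
            stringsAsFactors = FALSE)
        }
      }
    }
    counts <- do.call(rbind, blocks)
    md <- do.call(rbind, meta)
    cell_meta <- data.frame(
      type = rep(md$type, md$n), subtype = rep(md$subtype, md$n),
      batch = rep(md$batch, md$n), stringsAsFactors = FALSE)
    cell_meta$cell_id <- sprintf("%s_%05d", domain, seq_len(nrow(cell_meta)))
    cell_meta$status <- status[cell_meta$type]
    list(counts = counts, meta = cell_meta)
  }

  rd <- gen_domain("ref")
  qd <- gen_domain("query")
  # reference labels are the finest level available (subtype when present)
  ref_label <- if (ns > 1L) rd$meta$subtype else rd$meta$type
  ref <- annotated_matrix(rd$counts, genes, rd$meta$cell_id, rd$meta$batch,
                          label = ref_label)
  query <- annotated_matrix(qd$counts, genes, qd$meta$cell_id, qd$meta$batch)
  list(
    ref = ref, query = query,
    truth = list(
      ref_truth = rd$meta[, c("cell_id", "type", "subtype", "batch", "status")],
      query_truth = qd$meta[, c("cell_id", "type", "subtype", "batch", "status")],
      type_status = data.frame(type = types, status = unname(status),
                               stringsAsFactors = FALSE),
      markers = data.frame(gene = genes[unlist(marker_idx)],
                           type = rep(types, each = nm),
                           stringsAsFactors = FALSE)
    )
  )
}

#' Named fixture presets
#'
#' Canonical simulation scenarios used throughout the tests:
#' \describe{
#'   \item{easy}{full overlap, no batch effect; a sanity floor any competent
#'     classifier clears.}
#'   \item{partial_overlap}{one reference-only and one query-only
#'     (interfering) type on top of five shared types, two batches per
#'     domain, about 6000 cells.}
#'   \item{resolution_mismatch}{fine subtype-level reference labels with
#'     coarse query truth.}
#'   \item{cross_species}{weak shared signal and a large query-only
#'     fraction (5 of 8 query types, about 63 percent of query cells).}
#' }
#'
#' @param seed integer seed stored in every preset.
#' @return named list of \code{\link{sim_config}} objects.
#' @export
fixture_presets <- function(seed = 1L) {
  list(
    easy = sim_config(n_types_shared = 4L, n_types_ref_only = 0L,
                      n_types_query_only = 0L, n_genes = 300L,
                      n_marker_genes_per_type = 20L,
                      cells_per_type_per_batch = 120L,
                      n_ref_batches = 1L, n_query_batches = 1L,
                      batch_effect_sd = 0, dispersion = 0.15, seed = seed),
    partial_overlap = sim_config(n_types_shared = 5L, n_types_ref_only = 1L,
                                 n_types_query_only = 1L, n_genes = 500L,
                                 n_marker_genes_per_type = 20L,
                                 cells_per_type_per_batch = 250L,
                                 n_ref_batches = 2L, n_query_batches = 2L,
                                 batch_effect_sd = 0.3, dispersion = 0.15,
                                 seed = seed),
    resolution_mismatch = sim_config(n_types_shared = 4L, n_types_ref_only = 0L,
                                     n_types_query_only = 0L,
                                     subtypes_per_type = 2L, n_genes = 400L,
                                     n_marker_genes_per_type = 20L,
                                     cells_per_type_per_batch = 150L,
                                     n_ref_batches = 1L, n_query_batches = 1L,
                                     batch_effect_sd = 0.2,
                                     subtype_shift_sd = 0.8,
                                     dispersion = 0.15, seed = seed),
    cross_species = sim_config(n_types_shared = 3L, n_types_ref_only = 1L,
                               n_types_query_only = 5L, n_genes = 600L,
                               n_marker_genes_per_type = 15L,
                               cells_per_type_per_batch = 150L,
                               n_ref_batches = 1L, n_query_batches = 1L,
                               batch_effect_sd = 0.5, dispersion = 0.15,
                               seed = seed)
  )
}
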