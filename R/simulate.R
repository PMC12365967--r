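#' Configuration for the reference/query count simulator
#'
#' Describes a two-batch scRNA-seq experiment: a set of cell types shared
#' between a labeled reference and an unlabeled query, plus query-only novel
#' types. Each type owns a disjoint block of marker genes up-regulated by
#' \code{2^marker_lfc}; the query batch additionally carries a per-gene
#' multiplicative technical factor (log-normal with SD \code{batch_sd} on the
#' log scale); counts are negative binomial with mean \eqn{\mu} and variance
#' \eqn{\mu + \mu^2/\theta}; per-cell library sizes are log-normal.
#'
#' @param n_genes number of genes.
#' @param known_types data.frame with columns \code{name}, \code{n_ref},
#'   \code{n_query} (at least two types).
#' @param novel_types data.frame with columns \code{name}, \code{n_query};
#'   these types never appear in the reference.
#' @param n_markers marker genes per type (disjoint across types).
#' @param marker_lfc log2 fold change of marker genes in their own type.
#' @param batch_sd SD (log scale) of the per-gene query batch factor.
#' @param dispersion negative-binomial inverse-dispersion \eqn{\theta}.
#' @param libsize_meanlog,libsize_sdlog log-scale mean and SD of per-cell
#'   library sizes.
#' @param seed integer seed; generation is fully deterministic given the seed.
#' @return a \code{"sim_config"} list.
#' @export
sim_config <- function(n_genes = 2000L,
                       known_types = data.frame(
                         name = paste0("type", 1:5),
                         n_ref = 300L, n_query = 300L),
                       novel_types = data.frame(
                         name = c("novelA", "novelB"),
                         n_query = c(150L, 20L)),
                       n_markers = 50L,
                       marker_lfc = 4,
                       batch_sd = 0.3,
                       dispersion = 10,
                       libsize_meanlog = log(5000),
                       libsize_sdlog = 0.3,
                       seed = 20240101L) {
  known_types <- as.data.frame(known_types)
  novel_types <- as.data.frame(novel_types)
  if (nrow(known_types) < 2L) stop("need at least two known types")
  if (any(c(known_types$n_ref, known_types$n_query, novel_types$n_query) < 0))
    stop("cell counts must be non-negative")
  all_names <- c(known_types$name, novel_types$name)
  if (anyDuplicated(all_names)) stop("type names must be unique")
  n_types <- length(all_names)
  if (n_types * n_markers > n_genes)
    stop("marker demand (", n_types * n_markers, ") exceeds n_genes (", n_genes, ")")
  structure(list(n_genes = as.integer(n_genes), known_types = known_types,
                 novel_types = novel_types, n_markers = as.integer(n_markers),
                 marker_lfc = marker_lfc, batch_sd = batch_sd,
                 dispersion = dispersion, libsize_meanlog = libsize_meanlog,
                 libsize_sdlog = libsize_sdlog, seed = as.integer(seed)),
            class = "sim_config")
}

#' The default benchmark configuration ("simbench-1")
#'
#' 2,000 genes; five known types with 300 reference and 300 query cells each;
#' two query-only novel types of 150 and 20 cells (the 20-cell type probes
#' rare-population discovery); 50 markers per type at log2 fold change 4;
#' query batch factor SD 0.3; NB dispersion 10; seed 20240101. Sized so the
#' full pipeline runs in minutes on one CPU.
#'
#' @param seed override the fixture seed.
#' @return a \code{"sim_config"}.
#' @export
simbench1_config <- function(seed = 20240101L) sim_config(seed = seed)

#' Simulate a labeled reference and an unlabeled query count matrix
#'
#' @param config a [sim_config()].
#' @return list with \code{ref} ([expression_matrix()]), \code{ref_labels}
#'   (label table for all reference cells), \code{query}
#'   ([expression_matrix()]), and \code{truth} (a \code{"sim_truth"} list:
#'   per-cell \code{cells} data.frame with true type and batch, per-gene
#'   \code{genes} data.frame with baseline mean, marker assignment and batch
#'   factor, plus the config).
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  gene_ids <- sprintf("gene_%04d", seq_len(ng))
  base_mean <- stats::rlnorm(ng, meanlog = 0, sdlog = 1)

  types <- c(config$known_types$name, config$novel_types$name)
  marker_of <- rep(NA_character_, ng)
  marker_idx <- sample.int(ng, length(types) * config$n_markers)
  for (t in seq_along(types)) {
    sel <- marker_idx[((t - 1L) * config$n_markers + 1L):(t * config$n_markers)]
    marker_of[sel] <- types[t]
  }
  # per-type mean profiles: baseline with markers scaled by 2^lfc
  profiles <- vapply(types, function(ty) {
    m <- base_mean
    m[which(marker_of == ty)] <- m[which(marker_of == ty)] * 2^config$marker_lfc
    m
  }, numeric(ng))

  batch_factor <- stats::rlnorm(ng, meanlog = 0, sdlog = config$batch_sd)

  ref_type <- rep(config$known_types$name, config$known_types$n_ref)
  query_type <- c(rep(config$known_types$name, config$known_types$n_query),
                  rep(config$novel_types$name, config$novel_types$n_query))
  n_ref <- length(ref_type)
  n_query <- length(query_type)
  lib <- stats::rlnorm(n_ref + n_query, config$libsize_meanlog, config$libsize_sdlog)

  draw_cells <- function(type_vec, libs, use_batch) {
    out <- matrix(0L, ng, length(type_vec))
    for (j in seq_along(type_vec)) {
      prof <- profiles[, type_vec[j]]
      if (use_batch) prof <- prof * batch_factor
      mu <- libs[j] * prof / sum(prof)
      out[, j] <- stats::rnbinom(ng, size = config$dispersion, mu = mu)
    }
    out
  }
  ref_counts <- draw_cells(ref_type, lib[seq_len(n_ref)], use_batch = FALSE)
  query_counts <- draw_cells(query_type, lib[n_ref + seq_len(n_query)], use_batch = TRUE)

  ref_ids <- sprintf("ref_%05d", seq_len(n_ref))
  query_ids <- sprintf("query_%05d", seq_len(n_query))
  dimnames(ref_counts) <- list(gene_ids, ref_ids)
  dimnames(query_counts) <- list(gene_ids, query_ids)

  truth <- structure(list(
    cells = data.frame(cell_id = c(ref_ids, query_ids),
                       true_type = c(ref_type, query_type),
                       batch = rep(c("reference", "query"), c(n_ref, n_query)),
                       stringsAsFactors = FALSE),
    genes = data.frame(gene_id = gene_ids, base_mean = base_mean,
                       marker_of = marker_of, batch_factor = batch_factor,
                       stringsAsFactors = FALSE),
    config = config), class = "sim_truth")

  list(ref = expression_matrix(methods::as(Matrix::Matrix(ref_counts, sparse = TRUE),
                                           "CsparseMatrix"), batch = "reference"),
       ref_labels = data.frame(cell_id = ref_ids, label = ref_type,
                               stringsAsFactors = FALSE),
       query = expression_matrix(methods::as(Matrix::Matrix(query_counts, sparse = TRUE),
                                             "CsparseMatrix"), batch = "query"),
       truth = truth)
}

#' Remove whole cell types from a reference set
#'
#' Emulates hold-out benchmarks in which types present in the query are
#' withheld from the reference, turning them into unseen types.
#'
#' @param ref an [expression_matrix()] (reference batch).
#' @param ref_labels its label table.
#' @param types_to_drop character vector of type names to remove.
#' @return list with the reduced \code{ref} and \code{ref_labels}.
#' @export
holdout_types <- function(ref, ref_labels, types_to_drop) {
  ref_labels <- label_table(ref_labels)
  missing <- setdiff(types_to_drop, unique(ref_labels$label))
  if (length(missing))
    stop("type(s) absent from reference: ", paste(missing, collapse = ", "))
  remaining <- setdiff(unique(ref_labels$label), types_to_drop)
  if (length(remaining) < 2L)
    stop("holdout would leave fewer than 2 reference types")
  keep_cells <- ref_labels$cell_id[!ref_labels$label %in% types_to_drop]
  list(ref = expression_matrix(ref$counts[, keep_cells, drop = FALSE],
                               batch = ref$batch),
       ref_labels = ref_labels[ref_labels$cell_id %in% keep_cells, , drop = FALSE])
}
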