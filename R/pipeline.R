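#' Developmental stage labels of the reference dataset
#'
#' The ten embryonic stages of the annotated *Xenopus tropicalis*
#' single-cell atlas the pipeline is designed around.
#'
#' @return Character vector of ordered stage labels.
#' @export
xenopus_stages <- function() {
  as.character(c(8, 10, 11, 12, 13, 14, 16, 18, 20, 22))
}

annotation_cols <- c("stage", "cell_type", "parent_cell_type")

#' Read / write an annotated single-cell count table
#'
#' Tab-delimited text with one row per cell: the annotation columns
#' `stage`, `cell_type`, `parent_cell_type`, and one integer count
#' column per gene (already normalized/rounded by the provider; no
#' further normalization is applied). Rows with negative or non-integer
#' counts are dropped with a warning reporting how many; a stage label
#' outside `stage_levels` is an error naming the label.
#'
#' @param path File path.
#' @param stage_levels Ordered set of admissible stage labels.
#' @return A tibble with `stage` as a factor ordered by `stage_levels`.
#' @export
read_annotated_counts <- function(path, stage_levels = xenopus_stages()) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_count_table(tab, stage_levels)
}

#' @rdname read_annotated_counts
#' @param table An annotated count table.
#' @export
write_annotated_counts <- function(table, path) {
  out <- dplyr::mutate(table, stage = as.character(.data$stage))
  readr::write_tsv(out, path)
  invisible(path)
}

validate_count_table <- function(tab, stage_levels = xenopus_stages()) {
  missing <- setdiff(annotation_cols, names(tab))
  if (length(missing) > 0) {
    abort(paste0("missing annotation column(s): ", paste(missing, collapse = ", ")),
          class = "coexland_error_io")
  }
  tab$stage <- as.character(tab$stage)
  unknown <- setdiff(unique(tab$stage), stage_levels)
  if (length(unknown) > 0) {
    abort(paste0("unknown stage label(s): ", paste(unknown, collapse = ", ")),
          class = "coexland_error_stage")
  }
  genes <- setdiff(names(tab), annotation_cols)
  if (length(genes) == 0) {
    abort("table contains no gene count columns.", class = "coexland_error_io")
  }
  counts <- as.matrix(tab[, genes, drop = FALSE])
  bad <- rowSums(!is.finite(counts) | counts < 0 | counts %% 1 != 0) > 0
  if (any(bad)) {
    warn(sprintf("%d row(s) with negative or non-integer counts were dropped.", sum(bad)),
         class = "coexland_warning_rows")
    tab <- tab[!bad, , drop = FALSE]
  }
  tab$stage <- factor(tab$stage, levels = stage_levels)
  tibble::as_tibble(tab)
}

#' Specify a developmental lineage for one gene pair
#'
#' A lineage is a per-stage set of admissible cell types (typically a
#' branch-point cell type plus its parents at earlier stages and
#' daughters at later ones) together with the gene pair of interest.
#'
#' @param gene_x,gene_y Gene (column) names.
#' @param cell_types Either a character vector of cell types admissible
#'   at every stage, or a named list mapping stage labels to character
#'   vectors.
#' @param branch_stage Optional stage label where coexpression is
#'   maximal (annotation only).
#' @return A `lineage_spec`.
#' @export
lineage_spec <- function(gene_x, gene_y, cell_types, branch_stage = NULL) {
  structure(list(gene_x = gene_x, gene_y = gene_y,
                 cell_types = cell_types, branch_stage = branch_stage),
            class = "lineage_spec")
}

#' Filter a count table to the cells of a lineage
#'
#' Keeps, at each stage, only cells whose type belongs to the lineage's
#' set for that stage. The per-stage retained-cell counts are attached
#' as the `"stage_counts"` attribute.
#'
#' @param table An annotated count table.
#' @param spec A [lineage_spec()].
#' @return The filtered tibble.
#' @export
select_lineage_cells <- function(table, spec) {
  for (g in c(spec$gene_x, spec$gene_y)) {
    if (!g %in% names(table)) {
      abort(paste0("gene not present in table: ", g), class = "coexland_error_args")
    }
  }
  keep <- if (is.list(spec$cell_types)) {
    types <- spec$cell_types[as.character(table$stage)]
    mapply(function(ct, ty) !is.null(ty) && ct %in% ty, table$cell_type, types)
  } else {
    table$cell_type %in% spec$cell_types
  }
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    abort("no cells match the lineage at any stage.", class = "coexland_error_empty")
  }
  attr(out, "stage_counts") <- table(factor(as.character(out$stage),
                                            levels = levels(table$stage)))
  out
}

#' Estimate an empirical gene-pair landscape from cells
#'
#' Cells with either count above M-1 are dropped (the truncation
#' fraction is recorded); the remaining count pairs are binned into an
#' M x M frequency grid summing to 1, a sampled estimator of the
#' steady-state coexpression distribution.
#'
#' @param cells An annotated count table (already filtered to the cells
#'   of interest).
#' @param gene_pair Character vector of two gene column names.
#' @param M Grid size (counts 0..M-1).
#' @return A probability-form [coexpression_landscape()] with
#'   attributes `truncation_fraction` and `n_cells`.
#' @export
empirical_landscape <- function(cells, gene_pair, M = 21) {
  M <- check_M(M)
  x <- cells[[gene_pair[1]]]
  y <- cells[[gene_pair[2]]]
  if (is.null(x) || is.null(y)) {
    abort("gene pair not found in the table.", class = "coexland_error_args")
  }
  n0 <- length(x)
  if (n0 == 0) abort("no cells provided.", class = "coexland_error_empty")
  keep <- x <= M - 1 & y <= M - 1
  if (!any(keep)) {
    abort("all cells exceeded the count cap M-1.", class = "coexland_error_empty")
  }
  grid <- matrix(0, M, M)
  tab <- table(factor(x[keep], levels = 0:(M - 1)),
               factor(y[keep], levels = 0:(M - 1)))
  grid[] <- as.numeric(tab) / sum(keep)
  land <- coexpression_landscape(grid, "probability", "empirical")
  attr(land, "truncation_fraction") <- 1 - sum(keep) / n0
  attr(land, "n_cells") <- sum(keep)
  land
}

#' Quasipotential of an empirical landscape
#'
#' `phi = -ln(pi)` with unobserved count pairs replaced by a small
#' pseudo-probability before the log (default 1e-6, below the smallest
#' estimable frequency at the dataset's cell numbers).
#'
#' @param landscape A probability-form empirical landscape.
#' @param pseudo Positive pseudo-probability for unobserved cells.
#' @return A quasipotential-form landscape.
#' @export
empirical_quasipotential <- function(landscape, pseudo = 1e-6) {
  quasipotential(landscape, floor = pseudo)
}

#' Build a landscape-shape trajectory for one gene pair
#'
#' For each stage, in order: select the lineage's cells, estimate the
#' empirical landscape, transform to the shape-space's representation,
#' and project. Stages with no retained cells are dropped from the
#' trajectory and listed in the `"dropped_stages"` attribute.
#'
#' @param table An annotated count table.
#' @param spec A [lineage_spec()].
#' @param space A fitted [fit_shape_space()].
#' @param stage_order Ordered stage labels to walk through.
#' @param M Grid size; defaults to the space's.
#' @return A `shape_trajectory`: tibble with `stage`, `n_cells` and
#'   score columns `c1` ... `cn`, rows ordered by stage.
#' @export
build_trajectory <- function(table, spec, space, stage_order = xenopus_stages(),
                             M = space$M) {
  cells <- select_lineage_cells(table, spec)
  gene_pair <- c(spec$gene_x, spec$gene_y)
  rows <- list(); dropped <- character(0)
  for (st in stage_order) {
    sub <- cells[as.character(cells$stage) == st, , drop = FALSE]
    if (nrow(sub) == 0) { dropped <- c(dropped, st); next }
    land <- tryCatch(empirical_landscape(sub, gene_pair, M),
                     coexland_error_empty = function(e) NULL)
    if (is.null(land)) { dropped <- c(dropped, st); next }
    if (space$representation == "quasipotential") {
      land <- empirical_quasipotential(land, pseudo = space$floor)
    }
    sc <- project_landscape(land, space)
    rows[[st]] <- dplyr::bind_cols(
      tibble::tibble(stage = st, n_cells = attr(land, "n_cells") %||% nrow(sub)), sc)
  }
  if (length(rows) == 0) {
    abort("no stage retained any cells for this lineage.",
          class = "coexland_error_empty")
  }
  traj <- dplyr::bind_rows(rows)
  structure(traj, class = c("shape_trajectory", class(traj)),
            gene_pair = gene_pair, dropped_stages = dropped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coordinate matrix of a trajectory
#'
#' @param trajectory A `shape_trajectory` (or anything coercible to a
#'   numeric matrix of stage rows x component columns).
#' @return Numeric m x n matrix with stage labels as row names.
#' @export
trajectory_matrix <- function(trajectory) {
  if (inherits(trajectory, "shape_trajectory")) {
    sc <- grep("^c[0-9]+$", names(trajectory), value = TRUE)
    m <- as.matrix(trajectory[, sc, drop = FALSE])
    rownames(m) <- as.character(trajectory$stage)
    return(m)
  }
  as.matrix(trajectory)
}

#' Frobenius distance between two landscape-shape trajectories
#'
#' The square root of the summed squared differences of the stage-by-
#' component coordinate matrices (the Frobenius norm of A - B). The two
#' trajectories must cover the same stages and components.
#'
#' @param A,B Trajectories (`shape_trajectory` or matrices) of
#'   identical shape.
#' @return Nonnegative scalar.
#' @examples
#' trajectory_distance(matrix(0, 2, 2), matrix(c(3, 4, 0, 0), 2, 2))
#' @export
trajectory_distance <- function(A, B) {
  a <- trajectory_matrix(A); b <- trajectory_matrix(B)
  if (!all(dim(a) == dim(b))) {
    abort("trajectories have different shapes.", class = "coexland_error_shape")
  }
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b))) {
    abort("trajectories cover different stages.", class = "coexland_error_shape")
  }
  sqrt(sum((a - b)^2))
}

#' Hierarchically cluster landscape-shape trajectories
#'
#' Agglomerative clustering on the pairwise Frobenius trajectory
#' distances. The linkage defaults to average; the flat cut is by a
#' fixed number of clusters `k` or a height threshold `h` (exactly one
#' must be given).
#'
#' @param trajectories A named list of trajectories of identical shape.
#' @param k Number of clusters, or `NULL`.
#' @param h Dendrogram cut height, or `NULL`.
#' @param linkage `"average"`, `"complete"`, or `"ward.D2"`.
#' @return A tibble with `trajectory` and `cluster`; the `stats::hclust`
#'   tree and the distance matrix are attached as attributes `"hclust"`
#'   and `"dist"`.
#' @export
cluster_trajectories <- function(trajectories, k = NULL, h = NULL,
                                 linkage = c("average", "complete", "ward.D2")) {
  linkage <- match.arg(linkage)
  if (length(trajectories) < 2) {
    abort("need at least two trajectories.", class = "coexland_error_args")
  }
  if (is.null(k) == is.null(h)) {
    abort("give exactly one of `k` or `h`.", class = "coexland_error_args")
  }
  mats <- lapply(trajectories, trajectory_matrix)
  d0 <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) all(dim(m) == d0), logical(1)))) {
    abort("trajectories have inconsistent shapes.", class = "coexland_error_shape")
  }
  n <- length(mats)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- sqrt(sum((mats[[i]] - mats[[j]])^2))
    }
  }
  nm <- names(trajectories) %||% as.character(seq_len(n))
  dimnames(D) <- list(nm, nm)
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  labels <- if (!is.null(k)) stats::cutree(hc, k = k) else stats::cutree(hc, h = h)
  out <- tibble::tibble(trajectory = nm, cluster = unname(labels[nm]))
  attr(out, "hclust") <- hc
  attr(out, "dist") <- D
  out
}

#' Sample a synthetic annotated cell table from model landscapes
#'
#' Draws i.i.d. per-cell mRNA count pairs from each stage's probability
#' landscape, emulating the structure of an annotated single-cell count
#' table (stage, cell type, parent cell type, two gene columns). This
#' is the package's synthetic-data generator: it reproduces the
#' sampling noise of finite cell numbers per stage but none of the
#' technical noise (drop-outs, depth variation) of real experiments.
#'
#' @param landscapes Named list mapping stage labels to probability-form
#'   landscapes.
#' @param n_cells_per_stage Cells per stage (recycled across stages).
#' @param seed Integer seed applied locally, or `NULL`.
#' @param gene_pair Names for the two gene columns.
#' @param cell_type,parent_cell_type Annotation constants.
#' @return An annotated count tibble (stage levels = the list names).
#' @export
simulate_cells <- function(landscapes, n_cells_per_stage = 1000, seed = NULL,
                           gene_pair = c("gene_x", "gene_y"),
                           cell_type = "synthetic", parent_cell_type = "root") {
  stages <- names(landscapes)
  if (is.null(stages) || any(stages == "")) {
    abort("`landscapes` must be a named list keyed by stage label.",
          class = "coexland_error_args")
  }
  n_cells_per_stage <- rep_len(n_cells_per_stage, length(landscapes))
  draw_all <- function() {
    purrr::map2_dfr(stages, seq_along(stages), function(st, i) {
      land <- landscapes[[i]]
      if (!inherits(land, "coexpression_landscape") ||
          land$representation != "probability") {
        abort("each landscape must be in probability form.",
              class = "coexland_error_representation")
      }
      n <- n_cells_per_stage[i]
      if (n == 0) {
        return(tibble::tibble(stage = character(0), cell_type = character(0),
                              parent_cell_type = character(0),
                              "{gene_pair[1]}" := integer(0),
                              "{gene_pair[2]}" := integer(0)))
      }
      M <- land$M
      idx <- sample.int(M * M, size = n, replace = TRUE, prob = as.vector(land$grid))
      tibble::tibble(stage = st, cell_type = cell_type,
                     parent_cell_type = parent_cell_type,
                     "{gene_pair[1]}" := (idx - 1L) %% M,
                     "{gene_pair[2]}" := (idx - 1L) %/% M)
    })
  }
  tab <- if (is.null(seed)) draw_all() else withr::with_seed(seed, draw_all())
  tab$stage <- factor(tab$stage, levels = stages)
  tab
}
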