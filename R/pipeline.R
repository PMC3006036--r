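#' Pipeline configuration
#'
#' Collects every tunable of the map-interpretation pipeline with its
#' default. Defaults follow the method's standard constants where
#' one exists (blob radius 2.5 A, shift cutoff 0.11 A, 20 iterations,
#' drift limit 3.5 A, masking radius 1.3 A, 15-degree template rotations,
#' cluster size 6, inversion-sphere radius 1.56 A, hydrogen-bond targets
#' 2.16 / 1.85 A, correctness radii 1.5 A for phosphates and 1.0 A for
#' bases); the remaining constants (density cap, score constants k1/k2,
#' pair threshold, planarity floor, seed floor) are this package's decided
#' defaults. Every value is range-checked.
#'
#' @param density_cap Clamp level for [modify_density()] (sigma).
#' @param blob_radius,shift_tol,max_iter,max_drift,mask_radius,seed_min,max_blobs
#'   Blob-search parameters, see [blob_params()].
#' @param planarity_floor Minimum planarity for base fitting.
#' @param rotations In-plane rotation starts for [simplex_fit()].
#' @param cluster_size Solutions kept per kind per blob.
#' @param simplex_maxit Evaluation budget per simplex start.
#' @param pair_threshold Watson-Crick acceptance threshold.
#' @param k1,k2 Phosphate-score constants.
#' @param inversion_radius Inversion-correlation sphere radius (A).
#' @param n_base_blobs Number of top-ranked planar blobs to attempt base
#'   fitting on.
#' @param phos_dist_max,base_c1p_max,base_rmsd_max Evaluation radii (A).
#' @param fractions Coverage percentages for the r.n. table.
#' @return A validated named list of class `pipeline_config`.
#' @export
pipeline_config <- function(density_cap = 4.0,
                            blob_radius = 2.5, shift_tol = 0.11,
                            max_iter = 20L, max_drift = 3.5,
                            mask_radius = 1.3, seed_min = 1.0,
                            max_blobs = 500L,
                            planarity_floor = 0.25, rotations = 24L,
                            cluster_size = 6L, simplex_maxit = 150L,
                            pair_threshold = 1.5, k1 = 12, k2 = 2,
                            inversion_radius = 1.56,
                            n_base_blobs = 32L,
                            phos_dist_max = 1.5, base_c1p_max = 1.0,
                            base_rmsd_max = 1.0,
                            fractions = c(80, 90, 100)) {
  chk <- function(x, lo, hi, nm) {
    if (!is.numeric(x) || any(!is.finite(x)) || any(x < lo) || any(x > hi)) {
      stop(sprintf("config field %s out of range [%g, %g]", nm, lo, hi),
           call. = FALSE)
    }
  }
  chk(density_cap, 0.1, 100, "density_cap")
  chk(blob_radius, 0.5, 10, "blob_radius")
  chk(shift_tol, 1e-4, 1, "shift_tol")
  chk(max_iter, 1, 1000, "max_iter")
  chk(max_drift, 0.1, 50, "max_drift")
  chk(mask_radius, 0.1, 10, "mask_radius")
  chk(seed_min, 0, 100, "seed_min")
  chk(max_blobs, 1, 1e6, "max_blobs")
  chk(planarity_floor, 0, 0.5, "planarity_floor")
  chk(rotations, 1, 360, "rotations")
  chk(cluster_size, 1, 50, "cluster_size")
  chk(simplex_maxit, 10, 1e5, "simplex_maxit")
  chk(pair_threshold, -10, 3, "pair_threshold")
  chk(k1, 0, 100, "k1"); chk(k2, 0, 100, "k2")
  chk(inversion_radius, 0.5, 5, "inversion_radius")
  chk(n_base_blobs, 1, 1e4, "n_base_blobs")
  chk(phos_dist_max, 0.1, 10, "phos_dist_max")
  chk(base_c1p_max, 0.1, 10, "base_c1p_max")
  chk(base_rmsd_max, 0.1, 10, "base_rmsd_max")
  chk(fractions, 1, 100, "fractions")
  structure(as.list(environment())[c(
    "density_cap", "blob_radius", "shift_tol", "max_iter", "max_drift",
    "mask_radius", "seed_min", "max_blobs", "planarity_floor", "rotations",
    "cluster_size", "simplex_maxit", "pair_threshold", "k1", "k2",
    "inversion_radius", "n_base_blobs", "phos_dist_max", "base_c1p_max",
    "base_rmsd_max", "fractions")],
    class = "pipeline_config")
}

#' Run the full map-interpretation pipeline
#'
#' Composes the stages in order: density preparation (normalize, clamp,
#' optional protein masking), blob search, phosphate ranking, base fitting
#' on the top planar blobs, Watson-Crick pruning, and, when a reference
#' structure is supplied, evaluation of both candidate lists. When
#' `out_dir` is given, tab-separated candidate tables, a PDB of the placed
#' bases and a JSON run log (configuration, seed, stage tallies) are
#' written; outputs are byte-identical across reruns with the same inputs,
#' configuration and seed.
#'
#' @param map A [density_grid()] or path to a CCP4/MRC map.
#' @param config A [pipeline_config()].
#' @param reference Optional reference: PDB path or atom tibble.
#' @param mask_atoms Optional n x 3 matrix (or `x,y,z` data frame) of
#'   protein atoms to mask out before searching.
#' @param mask_atom_radius Masking radius in Angstrom (default 1.8).
#' @param out_dir Optional output directory.
#' @param seed Integer seed recorded in the log (the pipeline itself is
#'   deterministic; the seed feeds any noise stage the caller ran before).
#' @return An object of class `nucleoblob_result`: list with `blobs`,
#'   `phosphates`, `base_fits`, `pairing`, and (if reference given)
#'   `phosphate_eval`, `base_eval`; plus `config`.
#' @export
run_pipeline <- function(map, config = pipeline_config(), reference = NULL,
                         mask_atoms = NULL, mask_atom_radius = 1.8,
                         out_dir = NULL, seed = 1L) {
  if (is.character(map)) map <- read_map(map)
  stopifnot(inherits(map, "density_grid"))
  stage <- "prep"
  res <- tryCatch({
    if (!isTRUE(map$normalized)) map <- normalize_density(map)
    map <- modify_density(map, config$density_cap)
    if (!is.null(mask_atoms)) map <- mask_region(map, mask_atoms, mask_atom_radius)
    stage <- "blobs"
    bp <- blob_params(radius = config$blob_radius, shift_tol = config$shift_tol,
                      max_iter = config$max_iter, max_drift = config$max_drift,
                      mask_radius = config$mask_radius,
                      seed_min = config$seed_min, max_blobs = config$max_blobs)
    blobs <- find_blobs(map, bp)
    stage <- "phosphates"
    phos <- rank_phosphates(blobs, map, k1 = config$k1, k2 = config$k2,
                            radius = config$inversion_radius)
    stage <- "bases"
    ranked <- rank_base_blobs(blobs)
    ranked <- ranked[ranked$planarity >= config$planarity_floor, , drop = FALSE]
    ranked <- utils::head(ranked, config$n_base_blobs)
    templates <- list(base_template("purine"), base_template("pyrimidine"))
    fits <- dplyr::bind_rows(lapply(seq_len(nrow(ranked)), function(i) {
      fit_bases_at_blob(map, ranked[i, , drop = FALSE], templates,
                        planarity_floor = config$planarity_floor,
                        cluster_size = config$cluster_size,
                        rotations = config$rotations,
                        maxit = config$simplex_maxit)
    }))
    stage <- "pairing"
    pairing <- prune_by_pairing(fits, threshold = config$pair_threshold)
    out <- list(map = map, blobs = blobs, phosphates = phos,
                base_fits = fits, pairing = pairing, config = config,
                seed = seed)
    if (!is.null(reference)) {
      stage <- "evaluation"
      out$phosphate_eval <- evaluate_phosphates(
        phos, reference, fractions = config$fractions,
        dist_max = config$phos_dist_max, cell = map$cell)
      placed <- placed_base_fits(pairing)
      out$base_eval <- evaluate_bases(placed, reference, cell = map$cell,
                                      c1p_max = config$base_c1p_max,
                                      rmsd_max = config$base_rmsd_max)
    }
    out
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  if (!is.null(out_dir)) write_result(res, out_dir)
  structure(res, class = "nucleoblob_result")
}

#' Accepted base placements of a pairing
#'
#' The fits retained after Watson-Crick pruning: both members of every
#' accepted pair plus the single best fit of each unpaired blob.
#'
#' @param pairing A `base_pairing` from [prune_by_pairing()].
#' @return A fit tibble.
#' @export
placed_base_fits <- function(pairing) {
  paired <- if (nrow(pairing$pairs)) {
    dplyr::bind_rows(c(pairing$pairs$purine, pairing$pairs$pyrimidine))
  } else NULL
  singles <- pairing$singles
  if (!is.null(singles) && nrow(singles)) {
    singles <- singles[, setdiff(names(singles), "unpaired"), drop = FALSE]
  }
  out <- dplyr::bind_rows(paired, singles)
  out
}

write_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, name) {
    df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
    utils::write.table(format(as.data.frame(df), digits = 8, trim = TRUE),
                       file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wtsv(res$blobs, "blobs.tsv")
  wtsv(res$phosphates, "phosphates.tsv")
  if (nrow(res$pairing$pairs)) {
    wtsv(res$pairing$pairs[, c("blob_purine", "blob_pyrimidine", "wc_score")],
         "pairs.tsv")
  } else {
    wtsv(tibble::tibble(blob_purine = integer(), blob_pyrimidine = integer(),
                        wc_score = double()), "pairs.tsv")
  }
  placed <- placed_base_fits(res$pairing)
  if (nrow(placed)) {
    at <- dplyr::bind_rows(lapply(seq_len(nrow(placed)), function(i) {
      X <- placed$coords[[i]]
      nm <- rownames(X)
      tibble::tibble(chain = "A", resno = i,
                     resid = if (placed$kind[i] == "purine") "G" else "C",
                     name = nm,
                     element = vapply(nm, atom_element, character(1)),
                     x = X[, 1], y = X[, 2], z = X[, 3], b = 15)
    }))
    write_scene_pdb(at, file.path(out_dir, "bases.pdb"))
  }
  log <- list(
    config = unclass(res$config),
    seed = res$seed,
    config_hash = rlang::hash(unclass(res$config)),
    n_blobs = nrow(res$blobs),
    n_base_fits = nrow(res$base_fits),
    n_pairs = nrow(res$pairing$pairs)
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.nucleoblob_result <- function(x, ...) {
  cat("<nucleoblob_result>\n")
  cat(sprintf("  blobs: %d   phosphate candidates: %d   base fits: %d   pairs: %d\n",
              nrow(x$blobs), nrow(x$phosphates), nrow(x$base_fits),
              nrow(x$pairing$pairs)))
  if (!is.null(x$phosphate_eval)) {
    cat("  phosphate r.n.:\n")
    print(as.data.frame(x$phosphate_eval), row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Section heat-map of a density grid
#'
#' @param object A [density_grid()].
#' @param section Grid section (third-axis voxel index, 1-based); defaults
#'   to the middle section.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot density_grid
#' @export
autoplot.density_grid <- function(object, section = NULL, ...) {
  if (is.null(section)) section <- ceiling(object$dims[3] / 2)
  sl <- object$values[, , section]
  df <- expand.grid(i = seq_len(nrow(sl)), j = seq_len(ncol(sl)))
  df$rho <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$rho)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "a axis (voxels)", y = "b axis (voxels)",
                  fill = "density\n(sigma)")
}
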