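## End-to-end run orchestration: a YAML run configuration names the inputs
## per analysis stage; only requested stages run; every parameter that shaped
## a number is echoed into the report so results are re-derivable.

pipeline_defaults <- function() {
  list(eps = 1.5, min_points = 5L, contacts_cutoff = 3.0,
       s_max = 0.5, t = 0.01, bin_width = 0.1,
       stability_cutoff = 6.0, stability_occupancy = 0.8,
       nci_margin = 3.0, nci_spacing = 0.15)
}

#' Run the combined analysis pipeline
#'
#' Reads a run configuration (YAML file or equivalent list), runs the
#' requested stages, and writes delimited result tables plus a plain-text
#' report into `out_dir`. Recognized top-level config keys:
#' \describe{
#'   \item{orbitals}{`path` to a frontier-orbital table: computes reactivity
#'     descriptors, a formatted table and a gap ranking.}
#'   \item{trajectory}{`path` to a multi-model PDB plus `donor` and named
#'     `acceptors` selection expressions: HAD series, distribution and
#'     stability classification.}
#'   \item{cluster}{requires `trajectory`; `ligand` and `fit` selections:
#'     RMSD matrix, DBSCAN labels, medoids, contact residues of the first
#'     medoid frame.}
#'   \item{nci}{requires `trajectory` (first medoid or frame 1); `ligand`
#'     selection: interfacial NCI classification and cube files.}
#'   \item{esp}{requires `trajectory` or a `structure` path plus `charges`
#'     path: point-charge potential and shell extrema.}
#'   \item{rcs}{`path` to a table with label/diatropic/paratropic columns:
#'     net ring-current table.}
#'   \item{defaults}{overrides for any default parameter (eps, min_points,
#'     contacts_cutoff, s_max, t, bin_width, stability_cutoff,
#'     stability_occupancy, nci_margin, nci_spacing).}
#' }
#' All referenced files are checked before any computation starts. Given the
#' same config and inputs the run directory contents are deterministic.
#'
#' @param config path to a YAML file, or a list with the same shape.
#' @param out_dir output directory, created if missing.
#' @return Invisibly, a list with every stage's results.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  defaults <- utils::modifyList(pipeline_defaults(),
                                if (is.null(cfg$defaults)) list() else cfg$defaults)
  ## pre-flight: every referenced input must exist before anything runs
  paths <- c(cfg$orbitals$path, cfg$trajectory$path, cfg$structure$path,
             cfg$esp$charges, cfg$rcs$path)
  for (p in paths) if (!is.null(p) && !file.exists(p))
    stop(sprintf("input file not found: '%s'", p))
  for (stage in c("cluster", "nci"))
    if (!is.null(cfg[[stage]]) && is.null(cfg$trajectory))
      stop(sprintf("stage '%s' requires a 'trajectory' input", stage))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list(parameters = defaults)
  report <- c("flavoreact pipeline report", "",
              "parameters:",
              sprintf("  %s = %s", names(defaults),
                      vapply(defaults, format, "")))

  write_tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  if (!is.null(cfg$orbitals)) {
    orb <- read_orbital_table(cfg$orbitals$path)
    prof <- reactivity_profile(orb)
    fmt <- format_profile(prof, decimals = 1L, mode = "truncate")
    rank <- rank_compounds(prof, key = "gap", tie_tolerance = 0.05)
    write_tsv(prof, "descriptors.tsv")
    write_tsv(fmt, "descriptors_formatted.tsv")
    results$reactivity <- list(profile = prof, formatted = fmt, rank = rank)
    report <- c(report, "", "reactivity descriptors (eV, truncated to 1 decimal):",
                utils::capture.output(print(fmt, row.names = FALSE)),
                "gap ranking (descending, ties within 0.05 eV):",
                paste(" ", vapply(rank, paste, "", collapse = " == "),
                      collapse = " > "))
  }

  traj <- NULL
  if (!is.null(cfg$trajectory)) {
    traj <- read_trajectory(cfg$trajectory$path, format = "pdb")
    acc <- cfg$trajectory$acceptors
    series <- had_series(traj, cfg$trajectory$donor, acc)
    stab <- lapply(series, classify_stability,
                   cutoff = defaults$stability_cutoff,
                   occupancy = defaults$stability_occupancy)
    for (nm in names(series)) {
      write_tsv(series[[nm]], sprintf("had_series_%s.tsv", nm))
      dist <- distance_distribution(series[[nm]], defaults$bin_width)
      write_tsv(data.frame(bin_lo = utils::head(dist$bin_edges, -1),
                           bin_hi = dist$bin_edges[-1],
                           probability = dist$probability),
                sprintf("had_distribution_%s.tsv", nm))
    }
    results$had <- list(series = series, stability = stab)
    report <- c(report, "", "HAD stability:",
                sprintf("  %s: %s (bound fraction %.3f; cutoff %.1f A, occupancy %.2f)",
                        names(stab),
                        vapply(stab, `[[`, "", "state"),
                        vapply(stab, `[[`, 0, "bound_fraction"),
                        defaults$stability_cutoff, defaults$stability_occupancy))
  }

  if (!is.null(cfg$cluster)) {
    m <- ligand_rmsd_matrix(traj, cfg$cluster$ligand, cfg$cluster$fit)
    cl <- dbscan_poses(m, eps = defaults$eps, min_points = defaults$min_points)
    write_tsv(data.frame(frame = m$frame_ids, label = cl$labels), "cluster_labels.tsv")
    contacts <- NULL
    if (length(cl$medoid_frames)) {
      for (k in seq_along(cl$medoid_frames))
        write_structure(frame_structure(traj, cl$medoid_frames[k]),
                        file.path(out_dir, sprintf("medoid_cluster%d.pdb", k)),
                        format = "pdb")
      contacts <- contact_residues(frame_structure(traj, cl$medoid_frames[1L]),
                                   cfg$cluster$ligand,
                                   cutoff = defaults$contacts_cutoff)
      write_tsv(as.data.frame(contacts), "contacts.tsv")
    }
    results$cluster <- list(matrix = m, clusters = cl, contacts = contacts)
    report <- c(report, "",
                sprintf("clusters (eps %.2f A, minPts %d): %d found, %d noise frames",
                        defaults$eps, defaults$min_points,
                        length(cl$medoid_frames), sum(cl$labels == 0L)))
  }

  if (!is.null(cfg$nci)) {
    st <- if (!is.null(results$cluster) && length(results$cluster$clusters$medoid_frames))
      frame_structure(traj, results$cluster$clusters$medoid_frames[1L])
    else frame_structure(traj, 1L)
    nci <- interfacial_nci(st, cfg$nci$ligand, margin = defaults$nci_margin,
                           spacing = defaults$nci_spacing,
                           s_max = defaults$s_max, t = defaults$t)
    write_grid(nci_field_grid(nci$grid, "signed_rho"), st,
               file.path(out_dir, "nci_signed_rho.cube"))
    write_grid(nci_field_grid(nci$grid, "s"), st,
               file.path(out_dir, "nci_s.cube"))
    write_tsv(data.frame(category = names(nci$classification$counts),
                         count = as.integer(nci$classification$counts)),
              "nci_counts.tsv")
    results$nci <- nci
    report <- c(report, "",
                sprintf("NCI categories (s < %.2f, t = %.3g a.u.): attractive %d, vdW %d, repulsive %d",
                        defaults$s_max, defaults$t,
                        nci$classification$counts[["attractive"]],
                        nci$classification$counts[["vdw"]],
                        nci$classification$counts[["repulsive"]]))
  }

  if (!is.null(cfg$esp)) {
    st <- if (!is.null(cfg$structure)) read_structure(cfg$structure$path)
          else frame_structure(traj, 1L)
    q <- read_charges(cfg$esp$charges, n_atoms = nrow(st$atoms))
    box <- grid_from_box(apply(st$xyz, 2, min) - 4, apply(st$xyz, 2, max) + 4,
                         spacing = 0.4)
    ## nudge the origin off any lattice that could intersect a nucleus
    box$origin <- box$origin + 0.05
    pot <- point_charge_esp(st, q, box)
    ex <- esp_extrema(pot, st)
    write_grid(pot, st, file.path(out_dir, "esp.cube"))
    results$esp <- list(potential = pot, extrema = ex)
    report <- c(report, "",
                sprintf("ESP shell extrema (a.u.): min %.4f near atom %d, max %.4f near atom %d",
                        ex$min$value, ex$min$nearest_atom,
                        ex$max$value, ex$max$nearest_atom))
  }

  if (!is.null(cfg$rcs)) {
    df <- read_delim_table(cfg$rcs$path)
    tab <- ring_current_table(df)
    write_tsv(tab, "ring_currents.tsv")
    results$rcs <- tab
    report <- c(report, "", "ring currents (nA/T):",
                utils::capture.output(print(tab, row.names = FALSE)))
  }

  writeLines(report, file.path(out_dir, "report.txt"))
  invisible(results)
}
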