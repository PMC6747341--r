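# Orchestration of the full analysis workflow from a single config.

#' Build a run configuration
#'
#' Collects every stage parameter with an explicit seed for each stochastic
#' stage. Inputs may be given as file paths (`structure`, `parameters`,
#' `domains`, `trajectory`) or as in-memory objects (`system`, `traj`).
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    structure = NULL, parameters = NULL, domains = NULL, trajectory = NULL,
    system = NULL, traj = NULL, dt = 0.1,
    out_dir = "iondyn_out",
    temperature = 310,
    equilibration = "auto",     # ns, or "auto" for the entropy-plateau heuristic
    stages = c("geometry", "conformation", "dynamics", "solvation", "energetics"),
    ca_selection = "name CA",
    fel_grid = 100, k_conformations = 10, k_scan = 1:8,
    n_init = 50, n_boot = 1000, seed = 1,
    rdf_bin = 0.002, rdf_rmax = NULL,
    geometry_cutoff = 0.35,
    include_solvation_terms = FALSE,
    fit_covariance = TRUE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) stop("unknown config field(s): ",
                                paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

.provenance <- function(cfg) {
  ser <- cfg[!vapply(cfg, is.object, logical(1))]
  sprintf("config_hash=%s seed=%d", rlang::hash(ser), cfg$seed)
}

.write_tsv <- function(df, path, prov) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# iondyn ", prov), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis workflow
#'
#' Executes the enabled stages in order — equilibration detection, geometry
#' observables, dihedral PCA with landscape and conformational families,
#' cross-correlation and Cartesian PCA, ion hydration, ion energetics with
#' interaction entropy and outlier analysis — writing TSV/JSON/PDB outputs
#' into `out_dir`. Every output carries the config hash and seed, and reruns
#' with the same config and seeds are reproducible.
#'
#' @param cfg A `run_config`.
#' @return A list of stage results (also serialised under `out_dir`).
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  sys <- cfg$system
  if (is.null(sys)) {
    sys <- stage("load", load_system(cfg$structure, cfg$parameters, cfg$domains))
  }
  traj <- cfg$traj
  if (is.null(traj)) {
    traj <- stage("load", load_trajectory(cfg$trajectory, sys, dt = cfg$dt))
  }
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  prov <- .provenance(cfg)
  out <- list(provenance = prov)
  t0 <- Sys.time()
  log_stage <- function(name) {
    message(sprintf("[iondyn] %-12s t+%.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  ca <- select_atoms(sys, cfg$ca_selection)
  if (length(ca) == 0) ca <- which(sys$atoms$domain != "solvent")
  masses_ca <- sys$atoms$mass[ca]

  # Equilibration window
  log_stage("equilibrate")
  ent <- stage("equilibrate",
               configurational_entropy_series(traj, ca, masses_ca,
                                              cfg$temperature))
  cutoff <- if (identical(cfg$equilibration, "auto")) {
    detect_equilibration(ent)
  } else as.numeric(cfg$equilibration)
  wtraj <- if (cutoff > min(traj$times)) equilibrated_window(traj, cutoff) else traj
  out$equilibration <- list(cutoff_ns = cutoff, entropy = ent)
  .write_tsv(ent, file.path(cfg$out_dir, "entropy_vs_time.tsv"), prov)

  domains <- setdiff(unique(sys$atoms$domain), c("solvent", "ion", "other"))
  ions <- which(sys$atoms$domain == "ion")

  if ("geometry" %in% cfg$stages) {
    log_stage("geometry")
    out$geometry <- stage("geometry", {
      rg <- radius_of_gyration(wtraj, ca, masses_ca)
      rmsd_all <- rmsd_series(wtraj, ca)
      rmsd_dom <- lapply(domains, function(d) {
        s <- intersect(ca, which(sys$atoms$domain == d))
        if (length(s) >= 3) rmsd_series(wtraj, s) else NULL
      })
      names(rmsd_dom) <- domains
      rmsf <- rmsf_per_residue(wtraj, sys, ca)
      com <- list()
      if (length(domains) >= 2) {
        prs <- utils::combn(domains, 2, simplify = FALSE)
        for (pr in prs) {
          sa <- intersect(ca, which(sys$atoms$domain == pr[1]))
          sb <- intersect(ca, which(sys$atoms$domain == pr[2]))
          if (length(sa) > 0 && length(sb) > 0) {
            com[[paste(pr, collapse = "-")]] <-
              com_distance(wtraj, sa, sb, sys$atoms$mass[sa], sys$atoms$mass[sb])
          }
        }
      }
      mind <- if (!is.null(wtraj$box)) min_periodic_distance(wtraj, ca) else NULL
      .write_tsv(rg, file.path(cfg$out_dir, "rg.tsv"), prov)
      .write_tsv(rmsd_all, file.path(cfg$out_dir, "rmsd.tsv"), prov)
      .write_tsv(attr(rmsf, "per_residue"),
                 file.path(cfg$out_dir, "rmsf.tsv"), prov)
      list(rg = rg, rmsd = rmsd_all, rmsd_domains = rmsd_dom, rmsf = rmsf,
           com = com, min_periodic = mind)
    })
  }

  if ("conformation" %in% cfg$stages) {
    log_stage("conformation")
    out$conformation <- stage("conformation", {
      dh <- extract_dihedrals(wtraj, sys)
      pc <- dpca(dh)
      fel <- free_energy_landscape(pc, grid = cfg$fel_grid,
                                   temperature = cfg$temperature)
      k_use <- min(cfg$k_conformations, nrow(pc$projections))
      cm <- kmeans_cluster(pc$projections[, 1:2, drop = FALSE], k_use,
                           n_init = cfg$n_init, seed = cfg$seed)
      cen <- extract_centroids(cm, fel, pc, wtraj, sys,
                               dir = file.path(cfg$out_dir, "centroids"))
      scan <- kmeans_scan(pc$projections[, 1:2, drop = FALSE],
                          ks = cfg$k_scan[cfg$k_scan <= nrow(pc$projections)],
                          n_init = cfg$n_init, seed = cfg$seed)
      .write_tsv(tibble::tibble(time = wtraj$times,
                                dPC1 = pc$projections[, 1],
                                dPC2 = pc$projections[, 2]),
                 file.path(cfg$out_dir, "dpca_projections.tsv"), prov)
      .write_tsv(tidy(fel), file.path(cfg$out_dir, "fel_grid.tsv"), prov)
      jsonlite::write_json(
        list(provenance = prov, k = cm$k, sse = cm$sse, s_avg = cm$s_avg,
             sc = attr(scan, "sc"), sizes = cm$sizes,
             scan = as.data.frame(scan)),
        file.path(cfg$out_dir, "clusters.json"), auto_unbox = TRUE, digits = NA)
      list(pc = pc, fel = fel, clusters = cm, centroids = cen, scan = scan)
    })
  }

  if ("dynamics" %in% cfg$stages) {
    log_stage("dynamics")
    out$dynamics <- stage("dynamics", {
      cv <- covariance_matrix(wtraj, ca, fit = cfg$fit_covariance)
      dc <- dccm(cv, resid = sys$atoms$resid[ca])
      cp <- cartesian_pca(cv)
      .write_tsv(tidy(dc), file.path(cfg$out_dir, "dccm.tsv"), prov)
      .write_tsv(cp$pc_rmsf, file.path(cfg$out_dir, "pc_rmsf.tsv"), prov)
      jsonlite::write_json(
        list(provenance = prov,
             var_fraction = cp$var_fraction[1:min(10, length(cp$var_fraction))],
             var_fraction_internal =
               cp$var_fraction_internal[1:min(10, length(cp$var_fraction))],
             first5_internal = sum(cp$var_fraction_internal[1:5])),
        file.path(cfg$out_dir, "cpca_variance.json"), auto_unbox = TRUE,
        digits = NA)
      list(dccm = dc, cpca = cp)
    })
  }

  if ("solvation" %in% cfg$stages && length(ions) > 0) {
    log_stage("solvation")
    out$solvation <- stage("solvation", {
      wat_o <- which(sys$atoms$domain == "solvent" & sys$atoms$element == "O")
      res <- list()
      for (ion in ions) {
        lab <- sprintf("%s_%d", sys$atoms$resname[ion], sys$atoms$resid[ion])
        if (length(wat_o) > 0 && !is.null(wtraj$box)) {
          pr <- rdf(wtraj, ion, wat_o, bin_width = cfg$rdf_bin,
                    r_max = cfg$rdf_rmax)
          .write_tsv(tidy(pr),
                     file.path(cfg$out_dir, sprintf("rdf_%s.tsv", lab)), prov)
          res[[lab]] <- list(rdf = pr, shells = shell_boundaries(pr))
        }
      }
      res
    })
  }

  if ("energetics" %in% cfg$stages && length(ions) > 0) {
    log_stage("energetics")
    out$energetics <- stage("energetics", {
      prot <- which(!sys$atoms$domain %in% c("solvent", "ion"))
      res <- list()
      reports <- list()
      for (ion in ions) {
        lab <- sprintf("%s_%d", sys$atoms$resname[ion], sys$atoms$resid[ion])
        es <- interaction_energy(wtraj, sys, ion, prot)
        solv <- if (cfg$include_solvation_terms) {
          solvation_terms(wtraj, sys, ion)
        } else NULL
        rep <- binding_report(es, solv, temperature = cfg$temperature,
                              n_boot = cfg$n_boot, seed = cfg$seed, label = lab)
        sig <- significant_residues(es)
        geo <- assign_geometry(frame_coords(wtraj, n_frames(wtraj)), sys, ion,
                               cutoff = cfg$geometry_cutoff,
                               box = if (!is.null(wtraj$box))
                                 wtraj$box[n_frames(wtraj), ])
        sig_atoms <- which(sys$atoms$resid %in% sig$resid[sig$significant] &
                             sys$atoms$element %in% c("N", "O"))
        dists <- if (length(sig_atoms) > 0) {
          ion_site_distances(wtraj, sys, ion, sig_atoms)
        } else NULL
        .write_tsv(tidy(es),
                   file.path(cfg$out_dir, sprintf("energy_%s.tsv", lab)), prov)
        .write_tsv(sig,
                   file.path(cfg$out_dir, sprintf("residues_%s.tsv", lab)), prov)
        res[[lab]] <- list(energy = es, report = rep, significant = sig,
                           geometry = geo, distances = dists)
        reports[[lab]] <- rep
      }
      all_rep <- dplyr::bind_rows(reports)
      jsonlite::write_json(
        c(list(provenance = prov), list(binding = as.data.frame(all_rep))),
        file.path(cfg$out_dir, "binding_report.json"), auto_unbox = TRUE,
        digits = NA)
      res
    })
  }

  jsonlite::write_json(list(provenance = prov, stages = cfg$stages,
                            equilibration_ns = cutoff),
                       file.path(cfg$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}
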