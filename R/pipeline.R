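## Orchestration: simulate -> fit -> select -> report for the kinetics
## side, and batched measurement jobs for the geometry side.

#' Run the kinetics pipeline from a configuration
#'
#' For each requested design x rate-set, generates a seeded synthetic
#' family (or loads one from a manifest), fits the candidate schemes,
#' discriminates between them, and writes per-family fit results, the
#' model comparison, and a summary table.
#'
#' @param config list (or path to a YAML/JSON file) with fields:
#'   \describe{
#'     \item{`designs`}{character vector of built-in design names
#'       (`"plasmin"`, `"kallikrein"`, `"trypsin"`) and/or paths to
#'       curve-family manifests.}
#'     \item{`rates`}{data frame like [reference_rates()] (default) giving
#'       the generating truth per enzyme/inhibitor pair; only rows whose
#'       `enzyme` matches a built-in design name are simulated.}
#'     \item{`seed`}{integer base seed.}
#'     \item{`noise_sd`}{signal noise sd (default [noise_model()]'s).}
#'     \item{`duration`, `dt`}{sampling grid for built-in designs.}
#'     \item{`fixed`}{named list of parameters fixed in the fits.}
#'     \item{`out_dir`}{output directory (optional; no files written when
#'       absent).}
#'   }
#' @return List with one element per family: `family`, `selection`
#'   ([discriminate_schemes()] output), and `summary`
#'   ([inhibition_summary()]); plus `report` (the combined table) and
#'   the materialized `config`.
#' @export
run_kinetics <- function(config) {
  config <- load_config(config)
  defaults <- list(designs = c("plasmin", "kallikrein", "trypsin"),
                   rates = reference_rates(), seed = 1L,
                   noise_sd = noise_model()$sd,
                   duration = 1800, dt = 1, fixed = list(),
                   out_dir = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (!is.numeric(config$seed) || config$seed != round(config$seed))
    stop("run_kinetics: seed must be an integer")
  builtins <- builtin_designs(config$duration, config$dt)
  rates <- as.data.frame(config$rates)
  bad <- setdiff(rates$scheme, scheme_ids())
  if (length(bad))
    stop("run_kinetics: unknown scheme name(s): ", paste(bad, collapse = ", "))

  results <- list()
  counter <- 0L
  for (d in config$designs) {
    if (d %in% names(builtins)) {
      rows <- which(rates$enzyme == d)
      if (!length(rows))
        stop("run_kinetics: no rates provided for design '", d, "'")
      for (ri in rows) {
        counter <- counter + 1L
        truth <- rate_parameters(
          k_on = rates$k_on[ri], k_off = rates$k_off[ri],
          k_cat = if (!is.null(config$fixed$k_cat)) config$fixed$k_cat else 10,
          K_m = if (!is.null(config$fixed$K_m)) config$fixed$K_m else 200e-6)
        fam <- generate_family(
          builtins[[d]], rates$scheme[ri], truth,
          noise_model(config$noise_sd, seed = config$seed + counter))
        key <- paste(d, rates$inhibitor[ri], sep = "/")
        sel <- discriminate_schemes(fam, fixed = config$fixed)
        results[[key]] <- list(
          family = fam, selection = sel,
          summary = summary_from_fit(sel$fits[[sel$selected]],
                                     enzyme = d,
                                     inhibitor = rates$inhibitor[ri]))
      }
    } else if (file.exists(d)) {
      counter <- counter + 1L
      fam <- read_family(d)
      sel <- discriminate_schemes(fam, fixed = config$fixed)
      results[[d]] <- list(
        family = fam, selection = sel,
        summary = summary_from_fit(sel$fits[[sel$selected]],
                                   enzyme = fam$design$enzyme_name))
    } else {
      stop("run_kinetics: design '", d,
           "' is neither a built-in name nor an existing manifest")
    }
  }
  report <- inhibition_report(lapply(results, `[[`, "summary"))
  out <- list(results = results, report = report, config = config)
  if (!is.null(config$out_dir)) write_kinetics_outputs(out, config$out_dir)
  out
}

write_kinetics_outputs <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cbind(quantity = rownames(out$report), out$report),
            file.path(dir, "summary.csv"), row.names = FALSE)
  blocks <- lapply(out$results, function(r) {
    sel <- r$selection
    list(selected = sel$selected,
         estimates = as.list(sel$fits[[sel$selected]]$estimates),
         se = as.list(sel$fits[[sel$selected]]$se),
         comparison = sel$comparison$table,
         summary = unclass(r$summary))
  })
  jsonlite::write_json(blocks, file.path(dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (grepl("\\.json$", config)) {
      config <- jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML config requires the 'yaml' package")
      config <- yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  config
}

#' Run a batch of geometry measurements
#'
#' @param config list (or YAML/JSON path) with a `jobs` list; each job
#'   has `measurement` (one of `"distance"`, `"chi1"`, `"angles"`,
#'   `"sasa"`, `"buried"`, `"docking_angle"`, `"rmsd"`), `file` (PDB
#'   path; `file2` where two structures are compared) and
#'   measurement-specific selector fields (see the corresponding
#'   functions).  Duplicate jobs are deduplicated with a warning.
#'   Missing files are an error naming the path; nothing is skipped
#'   silently.
#' @return Data frame with one row per measurement: `measurement`,
#'   `value`, `units`, `file`, `detail`.
#' @export
run_geometry <- function(config) {
  config <- load_config(config)
  jobs <- config$jobs
  if (is.null(jobs) || !length(jobs)) stop("run_geometry: no jobs in config")
  sig <- vapply(jobs, function(j) paste(deparse(j), collapse = ""), "")
  if (anyDuplicated(sig)) {
    warning("run_geometry: duplicate measurement requests deduplicated")
    jobs <- jobs[!duplicated(sig)]
  }
  rows <- lapply(jobs, function(job) {
    for (f in c("file", "file2"))
      if (!is.null(job[[f]]) && !file.exists(job[[f]]))
        stop("run_geometry: missing structure file: ", job[[f]],
             " (supply the file; no network fetch is performed)")
    model <- read_structure(job$file)
    val <- switch(job$measurement,
      distance = atom_distance(model, job$selA, job$selB),
      chi1 = chi1(model, job$chain, job$resno)$value,
      angles = angles_at_center(model, job$center, job$substituents)$mean,
      sasa = sasa(model, probe = job$probe %||% 1.4,
                  slice = job$slice %||% 0.1)$total,
      buried = buried_area(model, job$selA, job$selB,
                           probe = job$probe %||% 1.4,
                           slice = job$slice %||% 0.1),
      docking_angle = docking_angle(model, read_structure(job$file2),
                                    job$protease_chain,
                                    job$inhibitor_chain),
      rmsd = ca_superpose(model, read_structure(job$file2),
                          job$chain, job$chain2 %||% job$chain)$rmsd,
      stop("run_geometry: unknown measurement '", job$measurement, "'"))
    units <- switch(job$measurement,
                    distance = "Angstrom", chi1 = "degrees",
                    angles = "degrees", sasa = "Angstrom^2",
                    buried = "Angstrom^2", docking_angle = "degrees",
                    rmsd = "Angstrom")
    data.frame(measurement = job$measurement, value = val, units = units,
               file = job$file,
               detail = paste(deparse(job[setdiff(names(job),
                                                  c("measurement", "file"))]),
                              collapse = ""),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Reference measurements on the deposited complex structures
#'
#' Runs, on user-supplied coordinate files of the microplasmin and
#' trypsin complexes with textilinin-1, the structural measurements
#' characterising the trapped tetrahedral-intermediate interface:
#' the catalytic-serine OG to P1 carbonyl-carbon distance in each
#' complex, the mean bond angle at that carbon, the buried
#' protease/inhibitor interface area, the buried area between the two
#' complexes of the asymmetric unit, and the inter-complex docking
#' angle.  Chains are identified by size (protease > 150 residues)
#' unless given explicitly.
#'
#' @param microplasmin_path,trypsin_path PDB files of the two complexes
#'   (deposited asymmetric units).  These must be supplied locally;
#'   nothing is downloaded.
#' @param ser_resno_micro,ser_resno_trypsin catalytic serine residue
#'   numbers (plasminogen numbering 741; chymotrypsinogen numbering 195).
#' @param p1_resno P1 arginine residue number of the inhibitor (17).
#' @return Data frame of measurements (`measurement`, `value`, `units`).
#' @export
deposited_structure_report <- function(microplasmin_path, trypsin_path,
                                       ser_resno_micro = 741,
                                       ser_resno_trypsin = 195,
                                       p1_resno = 17) {
  for (p in c(microplasmin_path, trypsin_path))
    if (!file.exists(p))
      stop("deposited_structure_report: missing structure file: ", p,
           " (supply the deposited coordinates locally)")
  mp <- read_structure(microplasmin_path)
  tr <- read_structure(trypsin_path)
  chains_of <- function(model) {
    prot <- model[!model$is_het & !model$is_water, ]
    sizes <- vapply(split(prot$resno, prot$chain),
                    function(r) length(unique(r)), 1L)
    list(protease = names(sizes)[sizes > 150],
         inhibitor = names(sizes)[sizes <= 150 & sizes > 20])
  }
  cm <- chains_of(mp)
  ct <- chains_of(tr)
  if (length(cm$protease) < 1 || length(cm$inhibitor) < 1 ||
      length(ct$protease) < 1 || length(ct$inhibitor) < 1)
    stop("deposited_structure_report: could not identify protease and ",
         "inhibitor chains by size")
  pcm <- cm$protease[1]
  icm <- cm$inhibitor[1]

  rows <- list()
  add <- function(name, value, units)
    rows[[length(rows) + 1]] <<- data.frame(measurement = name,
                                            value = value, units = units)
  add("ser_og_to_p1_c_microplasmin",
      atom_distance(mp, list(chain = pcm, resno = ser_resno_micro,
                             atom = "OG"),
                    list(chain = icm, resno = p1_resno, atom = "C")),
      "Angstrom")
  add("ser_og_to_p1_c_trypsin",
      atom_distance(tr, list(chain = ct$protease[1],
                             resno = ser_resno_trypsin, atom = "OG"),
                    list(chain = ct$inhibitor[1], resno = p1_resno,
                         atom = "C")),
      "Angstrom")
  tet <- angles_at_center(
    tr, list(chain = ct$inhibitor[1], resno = p1_resno, atom = "C"),
    list(list(chain = ct$inhibitor[1], resno = p1_resno, atom = "CA"),
         list(chain = ct$inhibitor[1], resno = p1_resno, atom = "O"),
         list(chain = ct$inhibitor[1], resno = p1_resno + 1, atom = "N"),
         list(chain = ct$protease[1], resno = ser_resno_trypsin,
              atom = "OG")))
  add("tetrahedral_angle_mean_trypsin", tet$mean, "degrees")
  add("buried_interface_microplasmin",
      buried_area(mp, list(chain = pcm), list(chain = icm)),
      "Angstrom^2")
  if (length(cm$protease) >= 2 && length(cm$inhibitor) >= 2) {
    add("buried_between_complexes_microplasmin",
        buried_area(mp, list(chain = c(pcm, icm)),
                    list(chain = c(cm$protease[2], cm$inhibitor[2]))),
        "Angstrom^2")
    add("docking_angle_microplasmin",
        docking_angle(mp, mp, cm$protease, cm$inhibitor),
        "degrees")
  }
  do.call(rbind, rows)
}
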