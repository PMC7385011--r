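#' Default pipeline configuration
#'
#' Every parameter defaults to the value documented in its stage's
#' function; the configuration round-trips through YAML.
#'
#' @param out_dir output directory for the stage tables.
#' @param seed integer seed driving every stochastic stage.
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("clefscope_run_"),
                            seed = 0L) {
  structure(list(
    input = list(pdb_dir = NULL, msa = NULL, domains_yaml = NULL,
                 simulate = TRUE),
    synthetic = list(n_gh9 = 450L, n_linker = 60L, n_cbm = 110L,
                     n_members = 8L, n_clusters = 4L),
    core = list(cutoff = 1.0, min_core = 20L, criterion = "per_column",
                reference = 1L),
    enm = list(cutoff = 15, gamma = 1, mode_range = c(7L, 18L)),
    surfaces = list(r_min = 0.8, min_len = 4L, min_separation = 10L,
                    probe = 1.4, radius = 3.0),
    pca = list(axes = c(1L, 3L), columns = "core"),
    groove = list(probe = 1.4, spacing = 0.5, min_volume = 50,
                  measurements = NULL),
    active_site = list(dock = NULL, cvg = NULL, is_ = NULL),
    out_dir = out_dir, seed = as.integer(seed), log_level = "info"),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unspecified keys keep the [pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- unclass(pipeline_config())
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(cfg[[k]]))
      cfg[[k]][names(user[[k]])] <- user[[k]]
    else cfg[[k]] <- user[[k]]
  }
  class(cfg) <- "pipeline_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE))
}

log_msg <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[clefscope] %s", sprintf(...)))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full structural-dynamics pipeline
#'
#' Executes the stages in analysis order — structure/alignment input (or
#' synthetic family generation), ensemble superposition and invariant-core
#' analysis, elastic-network modes with RMSF and DCCM, correlated-segment
#' and interaction-surface delineation, coordinate PCA with quadrant
#' clustering, groove measurement with cylinder approximation, and
#' active-site set algebra when residue lists are supplied. Each stage
#' writes a TSV into `cfg$out_dir`; a `summary.yaml` records parameters,
#' package version, seed and per-stage wall time. Any stage failure halts
#' the run with the stage name in the error.
#'
#' @param cfg a [pipeline_config()] (or path to a YAML file).
#' @return Named list of stage outputs (invisibly also on disk).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(name, t_start)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t_start, 3)

  ## -- structures_io ------------------------------------------------------
  t_s <- proc.time()[["elapsed"]]
  inputs <- stage("structures_io", {
    if (isTRUE(cfg$input$simulate)) {
      sp <- synthetic_spec(n_gh9 = cfg$synthetic$n_gh9,
                           n_linker = cfg$synthetic$n_linker,
                           n_cbm = cfg$synthetic$n_cbm,
                           n_members = cfg$synthetic$n_members,
                           n_clusters = cfg$synthetic$n_clusters,
                           seed = cfg$seed)
      base <- make_multidomain_structure(sp)
      fam <- make_family(base$structure, base$annotation, sp)
      list(structures = fam$structures, map = fam$map,
           annotation = base$annotation, reference = base$structure,
           family = fam, spec = sp)
    } else {
      paths <- list.files(cfg$input$pdb_dir, pattern = "\\.pdb$",
                          full.names = TRUE)
      if (!length(paths)) stop("no PDB files in ", cfg$input$pdb_dir)
      structures <- lapply(paths, read_structure)
      map <- read_alignment(cfg$input$msa, structures)
      ann <- read_domains_yaml(cfg$input$domains_yaml,
                               s = structures[[cfg$core$reference]])
      list(structures = structures, map = map, annotation = ann,
           reference = structures[[cfg$core$reference]],
           family = NULL, spec = NULL)
    }
  })
  tick("structures_io", t_s)
  log_msg(cfg, "loaded %d structures, %d ungapped columns",
          length(inputs$structures), length(inputs$map$ungapped_columns))

  ## -- superposition_core -------------------------------------------------
  t_s <- proc.time()[["elapsed"]]
  core <- stage("superposition_core",
    find_invariant_core(inputs$structures, inputs$map,
                        cutoff = cfg$core$cutoff,
                        min_core = cfg$core$min_core,
                        reference = cfg$core$reference,
                        criterion = cfg$core$criterion))
  write_tsv(core_table(core), file.path(cfg$out_dir, "core.tsv"))
  tick("superposition_core", t_s)
  log_msg(cfg, "invariant core: %d/%d columns", length(core$core_columns),
          length(core$columns))

  ## -- enm_dynamics -------------------------------------------------------
  t_s <- proc.time()[["elapsed"]]
  enm <- stage("enm_dynamics", {
    ref <- inputs$reference
    H <- build_hessian(ref, cutoff = cfg$enm$cutoff, gamma = cfg$enm$gamma)
    mr <- seq(cfg$enm$mode_range[1], cfg$enm$mode_range[2])
    modes <- normal_modes(H, n_modes = max(mr))
    prof <- mode_rmsf(modes, mode_range = mr)
    cmap <- dccm_map(modes, mode_range = mr, labels = ref$res_id)
    write_tsv(data.frame(mode = seq_along(modes$eigenvalues),
                         eigenvalue = modes$eigenvalues,
                         frequency_au = modes$frequencies),
              file.path(cfg$out_dir, "modes.tsv"))
    write_tsv(data.frame(res_id = ref$res_id,
                         domain = domain_of(inputs$annotation, ref$res_id),
                         rmsf_modes = prof$rmsf),
              file.path(cfg$out_dir, "rmsf.tsv"))
    utils::write.table(
      cbind(res_id = ref$res_id, as.data.frame(cmap$matrix)),
      file.path(cfg$out_dir, "dccm.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    list(modes = modes, rmsf = prof, dccm = cmap)
  })
  tick("enm_dynamics", t_s)

  ## -- interaction_surfaces -----------------------------------------------
  t_s <- proc.time()[["elapsed"]]
  surfaces <- stage("interaction_surfaces", {
    pairs <- correlated_segments(enm$dccm, inputs$annotation,
                                 res_id = inputs$reference$res_id,
                                 r_min = cfg$surfaces$r_min,
                                 min_len = cfg$surfaces$min_len,
                                 min_separation = cfg$surfaces$min_separation)
    surf <- classify_surfaces(pairs, inputs$annotation, s = inputs$reference,
                              probe = cfg$surfaces$probe,
                              radius = cfg$surfaces$radius)
    write_tsv(surf, file.path(cfg$out_dir, "surfaces.tsv"))
    list(pairs = pairs, surfaces = surf)
  })
  tick("interaction_surfaces", t_s)
  log_msg(cfg, "%d segment pairs, %d interaction surfaces",
          nrow(surfaces$pairs), nrow(surfaces$surfaces))

  ## -- pca_clustering -----------------------------------------------------
  t_s <- proc.time()[["elapsed"]]
  pca <- stage("pca_clustering", {
    fit_cols <- if (identical(cfg$pca$columns, "core"))
      core$core_columns else inputs$map$ungapped_columns
    ens <- superpose_ensemble(inputs$structures, inputs$map,
                              fit_columns = fit_cols,
                              reference = cfg$core$reference)
    p <- coordinate_pca(ens)
    k <- ncol(p$projections)
    ax <- pmin(cfg$pca$axes, k)
    quad <- quadrant_cluster(p, ax[1], ax[2])
    scores <- as.data.frame(p$projections)
    names(scores) <- paste0("pc", seq_len(k))
    write_tsv(cbind(structure = ens$names, scores, quadrant = quad),
              file.path(cfg$out_dir, "pca.tsv"))
    list(pca = p, quadrant = quad, axes = ax)
  })
  tick("pca_clustering", t_s)

  ## -- groove_geometry ----------------------------------------------------
  t_s <- proc.time()[["elapsed"]]
  groove <- stage("groove_geometry", {
    if (!is.null(cfg$groove$measurements)) {
      tab <- if (is.character(cfg$groove$measurements))
        read.delim(cfg$groove$measurements) else cfg$groove$measurements
      fit <- cylinder_table(tab[, c("A_o", "V_o")])
    } else {
      gl <- grid_groove_measure(inputs$reference,
                                probe = cfg$groove$probe,
                                spacing = cfg$groove$spacing,
                                min_volume = cfg$groove$min_volume)
      fit <- if (length(gl)) {
        tab <- data.frame(A_o = vapply(gl, `[[`, numeric(1), "A_o"),
                          V_o = vapply(gl, `[[`, numeric(1), "V_o"),
                          domains = vapply(gl, assign_groove_domains,
                                           character(1),
                                           domains = inputs$annotation))
        cylinder_table(tab)
      } else data.frame(A_o = numeric(0), V_o = numeric(0))
    }
    write_tsv(fit, file.path(cfg$out_dir, "grooves.tsv"))
    fit
  })
  tick("groove_geometry", t_s)

  ## -- active_site --------------------------------------------------------
  t_s <- proc.time()[["elapsed"]]
  active <- stage("active_site", {
    a <- cfg$active_site
    if (!is.null(a$dock) && !is.null(a$cvg)) {
      dock <- parse_residue_list(read_text(a$dock), "Dock")
      cvg <- parse_residue_list(read_text(a$cvg), "CvG")
      is_ <- if (!is.null(a$is_)) parse_residue_list(read_text(a$is_), "IS")
             else residue_set(integer(0)[FALSE], character(0), "IS")
      comb <- combine_active_site(dock, cvg, is_)
      comp <- composition(comb)
      df <- data.frame(res_id = comb$members$res_id, aa = comb$members$aa,
                       in_is = !paste0(comb$members$aa,
                                       comb$members$res_id) %in%
                         paste0(is_$members$aa, is_$members$res_id))
      write_tsv(df, file.path(cfg$out_dir, "activesite.tsv"))
      list(combined = comb, composition = comp)
    } else {
      ## default report: class composition of the published contact lists
      tabs <- active_site_table()
      comp <- lapply(tabs, composition)
      df <- data.frame(id = names(tabs),
                       n = vapply(comp, `[[`, numeric(1), "total"),
                       t(vapply(comp, `[[`, numeric(length(AA_CLASSES)),
                                "fractions")))
      write_tsv(df, file.path(cfg$out_dir, "activesite.tsv"))
      list(composition = comp)
    }
  })
  tick("active_site", t_s)

  summary <- list(package = "clefscope",
                  version = as.character(packageVersion("clefscope")),
                  seed = cfg$seed,
                  parameters = unclass(cfg)[c("core", "enm", "surfaces",
                                              "pca", "groove")],
                  wall_time_s = timings,
                  total_s = round(proc.time()[["elapsed"]] - t0, 3))
  yaml::write_yaml(summary, file.path(cfg$out_dir, "summary.yaml"))
  invisible(list(inputs = inputs, core = core, enm = enm,
                 surfaces = surfaces, pca = pca, groove = groove,
                 active_site = active, out_dir = cfg$out_dir,
                 summary = summary))
}

read_text <- function(path) paste(readLines(path), collapse = " ")
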