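#' Default pipeline configuration
#'
#' Returns the default run configuration: temperature 303 K, PCA frame
#' offset 10, wavelet scale grid 0.2-25 ns with step 1.01 and significance
#' constants (1.6094, 0.99), basin threshold 100 J/mol, and a small Gaussian
#' fixture. Any field can be overridden via `...` or a YAML config file.
#'
#' @param ... named overrides.
#' @return named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = "mdscope-run",
    fixture = list(kind = "gaussian", n_res = 60L, n_frames = 2000L,
                   dt_ps = 10),
    selection = "name CA",
    temperature = 303,
    pca_offset = 10L,
    n_modes = 10L,
    wavelet = list(scale_min = 0.2, scale_max = 25, factor = 1.01,
                   chi2_critical = 1.6094, confidence = 0.99),
    basin_threshold = 100,
    blocks = NULL
  )
  utils::modifyList(cfg, list(...))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order on one trajectory, writing every
#' stage's outputs and a manifest (config snapshot, package version, output
#' checksums) under `config$out_dir`. Stages: `simulate-fixture`, `align`,
#' `rmsf`, `pca`, `enm`, `dccm`, `wavelet`, `fel`, `hbond`, `report`.
#' Deterministic stages rerun bit-identically under the same config and seed.
#'
#' @param stages character vector of stage names (default: all).
#' @param config configuration list (see [default_config()]) or path to a
#'   YAML file of overrides.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(stages = c("simulate-fixture", "align", "rmsf",
                                    "pca", "enm", "dccm", "wavelet", "fel",
                                    "hbond", "report"),
                         config = default_config()) {
  if (is.character(config) && length(config) == 1L) {
    config <- utils::modifyList(default_config(), yaml::read_yaml(config))
  }
  known <- c("simulate-fixture", "align", "rmsf", "pca", "enm", "dccm",
             "wavelet", "fel", "hbond", "report")
  bad <- setdiff(stages, known)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("mdscope")),
                   config = config, stages = list())
  env <- new.env()
  tsv <- function(df, name) {
    p <- file.path(out, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  get_fixture <- function() {
    if (is.null(env$fix)) {
      fx <- config$fixture
      env$fix <- switch(fx$kind,
        gaussian = gen_gaussian_traj(n_res = fx$n_res, n_frames = fx$n_frames,
                                     dt_ps = fx$dt_ps, seed = config$seed),
        hinge = gen_two_domain_hinge(n_res = fx$n_res, n_frames = fx$n_frames,
                                     dt_ps = fx$dt_ps, seed = config$seed),
        `double-well` = gen_double_well(n_res = fx$n_res, n_frames = fx$n_frames,
                                        dt_ps = fx$dt_ps, seed = config$seed),
        stopf("unknown fixture kind '%s'", fx$kind))
    }
    env$fix
  }
  get_aligned <- function() {
    if (is.null(env$aligned)) {
      env$aligned <- align_trajectory(get_fixture()$trajectory, "average",
                                      config$selection)
    }
    env$aligned
  }
  get_pca <- function() {
    if (is.null(env$pca)) {
      env$pca <- pca_modes(get_aligned(), config$selection,
                           offset = config$pca_offset,
                           n_modes = config$n_modes)
    }
    env$pca
  }
  for (st in stages) {
    t0 <- proc.time()[["elapsed"]]
    files <- switch(st,
      "simulate-fixture" = {
        fix <- get_fixture()
        c(write_structure(fix$structure, file.path(out, "fixture.pdb")),
          write_trajectory(fix$trajectory, file.path(out, "fixture.dcd")))
      },
      "align" = {
        write_trajectory(get_aligned(), file.path(out, "aligned.dcd"))
      },
      "rmsf" = {
        prof <- rmsf_profile(get_aligned(), config$selection)
        tsv(data.frame(resid = prof$resid, rmsf_A = prof$rmsf,
                       bfactor_A2 = prof$bfactor), "rmsf.tsv")
      },
      "pca" = {
        modes <- get_pca()
        proj <- project_trajectory(get_aligned(), modes,
                                   selection = config$selection)
        kld <- kld_convergence(proj)
        c(tsv(data.frame(mode = seq_along(modes$values),
                         eigenvalue = modes$values,
                         fraction = modes$fractions[seq_along(modes$values)]),
              "pca_eigenvalues.tsv"),
          tsv(data.frame(time_ns = attr(proj, "times_ns"),
                         unclass(proj)[seq_len(nrow(proj)), , drop = FALSE]),
              "pca_projections.tsv"),
          tsv(data.frame(mode = seq_along(kld), kld = kld), "pca_kld.tsv"))
      },
      "enm" = {
        modes <- enm_modes(get_fixture()$structure, config$selection)
        fl <- mode_fluctuations(modes, 3L, config$temperature)
        c(tsv(data.frame(mode = seq_along(modes$values),
                         eigenvalue = modes$values), "enm_eigenvalues.tsv"),
          tsv(fl, "enm_bfactors.tsv"))
      },
      "dccm" = {
        map <- dccm_map(get_aligned(), config$selection, fit = FALSE)
        files <- write_dccm(map, file.path(out, "dccm.tsv"))
        if (!is.null(config$blocks)) {
          bs <- block_statistics(map, lapply(config$blocks, function(b) {
            if (length(b) == 2L) seq(b[1], b[2]) else b
          }))
          files <- c(files, tsv(bs, "dccm_blocks.tsv"))
        }
        files
      },
      "wavelet" = {
        wv <- config$wavelet
        scales <- build_scale_grid(wv$scale_min,
                                   min(wv$scale_max,
                                       n_frames(get_aligned()) *
                                         get_aligned()$dt_ps / 1000 / 2),
                                   wv$factor)
        map <- morlet_map(get_aligned(), config$selection, scales)
        sig <- significance_mask(map, wv$chi2_critical, wv$confidence)
        tb <- wavelet_table(map, sig)
        tsv(tb[tb$significant | !tb$edge, ], "wavelet.tsv")
      },
      "fel" = {
        proj <- project_trajectory(get_aligned(), get_pca(),
                                   selection = config$selection)
        fel <- fel_from_projections(proj, c(1, 2), temperature = config$temperature)
        basins <- extract_basins(fel, config$basin_threshold)
        p1 <- tsv(data.frame(x = rep(fel$x, times = length(fel$y)),
                             y = rep(fel$y, each = length(fel$x)),
                             g_jmol = as.numeric(fel$energy)), "fel.tsv")
        p2 <- file.path(out, "basins.json")
        jsonlite::write_json(lapply(basins, function(b) {
          list(occupancy = b$occupancy, min_energy = b$min_energy,
               centroid = b$centroid, n_cells = b$n_cells)
        }), p2, auto_unbox = TRUE, digits = NA)
        c(p1, p2)
      },
      "hbond" = {
        fix <- gen_hbond_fixture(seed = config$seed)
        hb <- hbond_occurrence(fix$trajectory, "resid 900", "not resid 900")
        tsv(hb, "hbonds.tsv")
      },
      "report" = {
        prof <- rmsf_profile(get_aligned(), config$selection)
        kld <- kld_convergence(project_trajectory(get_aligned(), get_pca(),
                                                  selection = config$selection))
        tsv(data.frame(
          quantity = c("n_frames", "n_atoms", "mean_rmsf_A", "kld_pc1",
                       "pca_top3_fraction"),
          value = c(n_frames(get_aligned()), n_atoms(get_aligned()),
                    mean(prof$rmsf), kld[1],
                    sum(get_pca()$fractions[1:3]))), "report.tsv")
      })
    manifest$stages[[st]] <- list(
      outputs = as.list(tools::md5sum(files)),
      wall_s = round(proc.time()[["elapsed"]] - t0, 3))
    message(sprintf("[mdscope] stage %-17s %6.2fs  %s", st,
                    manifest$stages[[st]]$wall_s,
                    paste(basename(files), collapse = ", ")))
  }
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
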