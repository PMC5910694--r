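# End-to-end pipeline orchestration: dti -> geometry -> tract -> fascicle
# -> architecture summary, with a YAML config, deterministic seeding and a
# run manifest.

#' Default pipeline configuration
#'
#' @return nested list of defaults; see the fields in the methods vignette
#' @export
default_config <- function() {
  list(
    phantom = list(preset = "four_slab", arc_radius_mm = Inf,
                   noise_sigma = 0, from_dwi = FALSE),
    paths = list(tensor = NULL, dwi = NULL, bvalbvec_stem = NULL,
                 labels = NULL, out = "myotract_out"),
    label_map = list(MA = 1, LA = 2, MP = 3, LP = 4),
    long_axis = "auto",
    tracking = list(fa_min = 0.1, fa_max = 0.5, md_min = 1e-3, md_max = 2e-3,
                    max_angle_deg = 10, step_mm = 1, min_length_mm = 15,
                    max_length_mm = 200, n_target = 1000, interp = "trilinear"),
    filters = list(max_extension_mm = 20, max_extension_fraction = 0.5),
    rng_seed = 1,
    log_level = "info"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Missing fields are filled from [default_config()].
#'
#' @param path YAML file path, or `NULL` for pure defaults
#' @return configuration list
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

config_tracking_params <- function(cfg, rng_seed = cfg$rng_seed) {
  tr <- cfg$tracking
  tracking_params(
    fa_min = tr$fa_min, fa_max = tr$fa_max,
    md_min = tr$md_min, md_max = tr$md_max,
    max_angle_deg = tr$max_angle_deg, step_mm = tr$step_mm,
    min_length_mm = tr$min_length_mm, max_length_mm = tr$max_length_mm,
    n_target = tr$n_target, interp = tr$interp, rng_seed = as.integer(rng_seed)
  )
}

pipeline_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message("[myotract] ", ...)
}

#' Run the full architecture pipeline
#'
#' Stages, in order: input (phantom generation or file loading), tensor
#' fitting (when starting from DWI), eigen maps, surface models and masks,
#' per-compartment tractography, fascicle reconstruction and filtering,
#' and the per-compartment architecture summary. All randomness derives
#' from `rng_seed` (per-compartment tracking substreams are
#' `rng_seed + label`); identical config and seed give identical outputs.
#' A manifest with the config hash, seed, versions and per-stage counts is
#' written alongside the outputs.
#'
#' @param config configuration list from [read_config()], or a path to a
#'   YAML config
#' @param write_outputs write NIfTI/mesh/CSV/manifest outputs under
#'   `config$paths$out` (default TRUE); the result list is returned either
#'   way
#' @return list with `eigenmaps`, `meshes`, `axis`, `muscle_length_mm`,
#'   `streamlines`, `fascicles` (per-fascicle table), `architecture`
#'   (per-compartment summary), `truth` (phantom runs), `manifest`
#' @export
run_pipeline <- function(config = default_config(), write_outputs = TRUE) {
  if (is.character(config)) config <- read_config(config)
  out_dir <- config$paths$out
  if (write_outputs && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  stage <- "input"
  result <- tryCatch({
    truth <- NULL
    if (!is.null(config$phantom)) {
      pipeline_log(config, "generating phantom (preset ",
                   config$phantom$preset, ")")
      if (!identical(config$phantom$preset, "four_slab")) {
        stop("unknown phantom preset: ", config$phantom$preset)
      }
      spec <- phantom_four_slab(
        arc_radius_mm = config$phantom$arc_radius_mm %||% Inf,
        noise_sigma = config$phantom$noise_sigma %||% 0,
        rng_seed = as.integer(config$rng_seed)
      )
      ph <- generate_phantom(spec)
      labels <- ph$labels
      truth <- ph$truth
      if (isTRUE(config$phantom$from_dwi) ||
            (config$phantom$noise_sigma %||% 0) > 0) {
        stage <- "dti"
        dwi <- synthesize_dwi(ph$tensors, s0 = spec$s0,
                              noise_sigma = spec$noise_sigma,
                              rng_seed = spec$rng_seed)
        tensors <- fit_tensor(dwi$dwi, b_value = 500,
                              directions = dwi$bvecs[-1, , drop = FALSE],
                              b0 = dwi$b0, affine = dwi$affine,
                              mask = ph$tensors$mask)
      } else {
        tensors <- ph$tensors
      }
    } else {
      p <- config$paths
      if (!is.null(p$tensor)) {
        nii <- read_nifti(p$tensor)
        tensors <- tensor_volume(nii$data, nii$affine)
      } else if (!is.null(p$dwi)) {
        stage <- "dti"
        nii <- read_nifti(p$dwi)
        bb <- read_bval_bvec(p$bvalbvec_stem)
        is_b0 <- bb$bvals == 0
        if (!any(is_b0)) stop("no b = 0 volume in ", p$bvalbvec_stem)
        b0 <- nii$data[, , , which(is_b0)[1]]
        tensors <- fit_tensor(
          nii$data[, , , !is_b0, drop = FALSE],
          b_value = max(bb$bvals),
          directions = bb$bvecs[!is_b0, , drop = FALSE],
          b0 = b0, affine = nii$affine
        )
      } else {
        stop("config must provide a phantom block or tensor/dwi paths")
      }
      lab <- read_nifti(p$labels)
      labels <- label_volume(array(as.integer(round(lab$data)),
                                   dim(lab$data)[1:3]), lab$affine)
    }

    stage <- "dti"
    pipeline_log(config, "computing eigen maps")
    em <- eigen_maps(tensors)

    stage <- "geometry"
    lm_ <- config$label_map
    comp_names <- names(lm_)
    pipeline_log(config, "building surfaces for ",
                 paste(comp_names, collapse = ", "))
    meshes <- stats::setNames(
      lapply(lm_, function(lb) build_surface(labels, lb)), comp_names
    )
    axis <- if (identical(config$long_axis, "auto")) {
      if (!is.null(config$phantom)) {
        # phantom runs: the prescribed long axis is known a priori, like
        # the manually picked anterior-surface points on real scans
        adir <- spec$compartments[[1]]$long_axis
        ctr <- colMeans(do.call(rbind, lapply(meshes, function(m) m$vertices)))
        long_axis(proximal = ctr + 100 * adir, distal = ctr - 100 * adir)
      } else {
        long_axis_auto(meshes)
      }
    } else {
      long_axis(unlist(config$long_axis$proximal),
                unlist(config$long_axis$distal))
    }
    mlen <- muscle_length(meshes, axis)
    shape <- dim(em$fa)
    masks <- make_seed_and_boundary_masks(labels, em$affine, shape)

    stage <- "tract"
    streamlines <- list()
    for (nm in comp_names) {
      lb <- as.character(lm_[[nm]])
      params <- config_tracking_params(config,
                                       rng_seed = config$rng_seed + lm_[[nm]])
      pipeline_log(config, "tracking ", nm)
      streamlines[[nm]] <- track_compartment(em, masks[[lb]], params)
      pipeline_log(config, nm, ": ", length(streamlines[[nm]]),
                   " accepted tracts (",
                   attr(streamlines[[nm]], "n_attempts"), " seeds)")
    }

    stage <- "fascicle"
    fl <- config$filters
    fascicles <- do.call(rbind, lapply(comp_names, function(nm) {
      reconstruct_fascicles(
        streamlines[[nm]], meshes[[nm]], axis, compartment = nm,
        max_extension_mm = fl$max_extension_mm,
        max_extension_fraction = fl$max_extension_fraction
      )
    }))

    stage <- "arch_stats"
    arch <- do.call(rbind, lapply(comp_names, function(nm) {
      f <- fascicles[fascicles$compartment == nm & fascicles$accepted, ]
      vol <- mesh_volume(meshes[[nm]])
      mlen_f <- mean(f$length_mm)
      data.frame(
        compartment = nm,
        n_tracked = sum(fascicles$compartment == nm),
        n_accepted = nrow(f),
        volume_cm3 = vol,
        fascicle_length_mm = mlen_f,
        pennation_deg = mean(f$pennation_deg),
        curvature_per_m = mean(f$curvature_per_m),
        pcsa_cm2 = if (nrow(f)) pcsa(vol, mlen_f) else NA_real_,
        normalized_fascicle_length =
          if (nrow(f)) normalized_fascicle_length(mlen_f, mlen) else NA_real_
      )
    }))

    manifest <- list(
      package = "myotract",
      version = as.character(utils::packageVersion("myotract")),
      r_version = R.version.string,
      rng_seed = config$rng_seed,
      filter_semantics = paste(
        "total length = fitted polynomial arc length + both extensions;",
        "'extended by' = sum of both ends' extensions;",
        "both bounds strict (<)"
      ),
      counts = list(
        n_streamlines = vapply(streamlines, length, integer(1)),
        n_fascicles_accepted = stats::setNames(arch$n_accepted,
                                               arch$compartment)
      )
    )

    res <- list(
      eigenmaps = em, meshes = meshes, axis = axis,
      muscle_length_mm = mlen, streamlines = streamlines,
      fascicles = fascicles, architecture = arch, truth = truth,
      manifest = manifest, config = config
    )

    if (write_outputs) {
      cfg_path <- file.path(out_dir, "config.yaml")
      yaml::write_yaml(config_serialisable(config), cfg_path)
      manifest$config_md5 <- unname(tools::md5sum(cfg_path))
      write_nifti(em$fa, file.path(out_dir, "fa.nii"), em$affine)
      write_nifti(em$md, file.path(out_dir, "md.nii"), em$affine)
      write_nifti(primary_eigenvector_rgb(em),
                  file.path(out_dir, "e1_rgb.nii"), em$affine)
      for (nm in comp_names) {
        write_ply(meshes[[nm]], file.path(out_dir, paste0("surface_", nm, ".ply")))
        write_streamlines_csv(streamlines[[nm]],
                              file.path(out_dir, paste0("tracts_", nm, ".csv")))
        write_streamlines_vtk(streamlines[[nm]],
                              file.path(out_dir, paste0("tracts_", nm, ".vtk")))
      }
      utils::write.csv(fascicles, file.path(out_dir, "fascicles.csv"),
                       row.names = FALSE)
      utils::write.csv(arch, file.path(out_dir, "architecture.csv"),
                       row.names = FALSE)
      if (!is.null(truth)) {
        utils::write.csv(truth, file.path(out_dir, "phantom_truth.csv"),
                         row.names = FALSE)
      }
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      res$manifest <- manifest
    }
    res
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}

# YAML cannot represent Inf portably; serialise as string
config_serialisable <- function(cfg) {
  if (!is.null(cfg$phantom) && is.infinite(cfg$phantom$arc_radius_mm)) {
    cfg$phantom$arc_radius_mm <- "Inf"
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
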