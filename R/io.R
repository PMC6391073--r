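#' Load a MaxQuant-style proteinGroups table
#'
#' Reads a tab-separated proteinGroups export and assembles an
#' [intensity_matrix()]. Sample columns are recognized by the
#' `"LFQ intensity <sample>"` and `"iBAQ <sample>"` prefixes; zero
#' intensities are treated as missing. The sample-to-condition mapping is
#' explicit (no filename parsing): supply a `sample_groups` tibble.
#'
#' @param path Path to the TSV file.
#' @param sample_groups Tibble with columns `sample` and `group` covering
#'   every LFQ sample column.
#' @return An [intensity_matrix()].
#' @export
load_protein_groups <- function(path, sample_groups) {
  d <- readr::read_tsv(path, show_col_types = FALSE,
                       na = c("", "NA", "NaN"), guess_max = Inf)
  required <- c("Majority protein IDs", "Peptides", "Potential contaminant",
                "Reverse")
  miss <- setdiff(required, names(d))
  if (length(miss) > 0) {
    abort(paste("proteinGroups file is missing required columns:",
                paste(miss, collapse = ", ")))
  }
  lfq_cols <- grep("^LFQ intensity .+", names(d), value = TRUE)
  if (length(lfq_cols) == 0) abort("no 'LFQ intensity <sample>' columns found")
  samples <- sub("^LFQ intensity ", "", lfq_cols)
  ibaq_cols <- paste0("iBAQ ", samples)
  has_ibaq <- all(ibaq_cols %in% names(d))
  ids <- d[["Majority protein IDs"]]
  if (anyDuplicated(ids)) {
    abort(paste("duplicated protein ids:",
                paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  miss_s <- setdiff(samples, sample_groups$sample)
  if (length(miss_s) > 0) {
    abort(paste("sample_groups has no group for sample(s):",
                paste(miss_s, collapse = ", ")))
  }
  samples_tbl <- tibble(sample = samples) |>
    dplyr::left_join(sample_groups, by = "sample")
  proteins <- tibble(
    protein_id = ids,
    peptides = as.integer(d$Peptides),
    contaminant = !is.na(d[["Potential contaminant"]]) &
      d[["Potential contaminant"]] == "+",
    reverse = !is.na(d$Reverse) & d$Reverse == "+"
  )
  lfq <- as.matrix(d[lfq_cols])
  ibaq <- if (has_ibaq) as.matrix(d[ibaq_cols]) else NULL
  intensity_matrix(proteins, samples_tbl, lfq, ibaq)
}

#' Write an intensity matrix as a MaxQuant-style proteinGroups TSV
#'
#' Inverse of [load_protein_groups()]: missing intensities are written as 0
#' and flags as `"+"`/empty, so a load/write cycle reproduces the file.
#'
#' @param im An [intensity_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(im, path) {
  stopifnot(inherits(im, "intensity_matrix"))
  zero <- function(m) {
    m[is.na(m)] <- 0
    m
  }
  d <- tibble(
    `Majority protein IDs` = im$proteins$protein_id,
    Peptides = im$proteins$peptides
  )
  lfq <- zero(im$lfq)
  colnames(lfq) <- paste0("LFQ intensity ", im$samples$sample)
  d <- dplyr::bind_cols(d, as_tibble(lfq))
  if (!is.null(im$ibaq)) {
    ibaq <- zero(im$ibaq)
    colnames(ibaq) <- paste0("iBAQ ", im$samples$sample)
    d <- dplyr::bind_cols(d, as_tibble(ibaq))
  }
  d[["Potential contaminant"]] <- ifelse(im$proteins$contaminant, "+", "")
  d$Reverse <- ifelse(im$proteins$reverse, "+", "")
  readr::write_tsv(d, path)
  invisible(path)
}

#' Write sample-group mapping as TSV
#'
#' @param im An [intensity_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_groups <- function(im, path) {
  readr::write_tsv(im$samples, path)
  invisible(path)
}

run_stage <- function(manifest, name, expr) {
  res <- tryCatch(list(ok = TRUE, value = expr),
                  error = function(e) list(ok = FALSE, error = conditionMessage(e)))
  manifest$stages[[name]] <- if (res$ok) {
    list(status = "ok")
  } else {
    list(status = "failed", error = res$error)
  }
  list(manifest = manifest, value = if (res$ok) res$value else NULL,
       ok = res$ok)
}

#' Run the full analysis workflow
#'
#' Executes the proteomics branch (filter, classify, cluster, and -- when
#' annotations are supplied -- GO-slim enrichment, plus absolute
#' quantification when a calibration is supplied) and the model branch
#' (grid-search fit when observations are supplied, then the light-response
#' and clamped-fraction experiments) from one declarative configuration,
#' writing TSV/JSON outputs and a machine-readable run manifest.
#'
#' @param config A list. Recognized entries:
#' \describe{
#'   \item{seed}{Integer seed recorded in the manifest and used for
#'     synthetic stages.}
#'   \item{proteomics}{Either a list of [simulate_proteomics()] arguments
#'     (synthetic run), or `list(path =, sample_groups =)` pointing to a
#'     proteinGroups TSV and its mapping.}
#'   \item{alpha, min_samples, p_adjust, missing_rule, k}{Options forwarded
#'     to the classification/filter/cluster steps.}
#'   \item{annotations}{`list(annotations =, slim =)`: tibbles or TSV paths
#'     for [map_go_slim()].}
#'   \item{calibration}{Arguments for [calibration_spec()]; enables
#'     [normalize_ibaq()] + [calibrate_absolute()], and with
#'     `complex_library` (path or list) also [complex_abundance_table()].}
#'   \item{model}{`list(params =, observations =, grid =, light =,
#'     constrained =)`: enables [grid_fit()] (observations + grid),
#'     [light_response()] (light vector) and [constrained_growth()]
#'     (list of `class_id`/`phi_Z`).}
#'   \item{out_dir}{Directory for output files; created if needed. When
#'     `NULL`, nothing is written.}
#' }
#' @return Invisibly, a list with the stage results and the `manifest`.
#' @export
run_pipeline <- function(config) {
  manifest <- list(
    package = as.character(utils::packageVersion("cyanogrowth")),
    seed = config$seed %||% NA,
    stages = list()
  )
  results <- list()
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(obj, file, writer = readr::write_tsv) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, file))
  }
  as_table <- function(x) {
    if (is.character(x)) readr::read_tsv(x, show_col_types = FALSE) else
      as_tibble(x)
  }

  # ---- proteomics branch ----
  if (!is.null(config$proteomics)) {
    pc <- config$proteomics
    st <- run_stage(manifest, "input", {
      if (!is.null(pc$path)) {
        load_protein_groups(pc$path, as_table(pc$sample_groups))
      } else {
        pc$seed <- pc$seed %||% config$seed
        do.call(simulate_proteomics, pc)$matrix
      }
    })
    manifest <- st$manifest
    im <- st$value
    if (!is.null(im)) {
      manifest$stages$input$n_proteins <- nrow(im$proteins)
      manifest$stages$input$n_samples <- nrow(im$samples)
      st <- run_stage(manifest, "filter", {
        filter_protein_groups(
          im, missing_rule = config$missing_rule %||% "complete_in_any_group")
      })
      manifest <- st$manifest
      filtered <- st$value
      if (!is.null(filtered)) {
        manifest$stages$filter$n_retained <- nrow(filtered$proteins)
        results$filtered <- filtered
        st <- run_stage(manifest, "classify", {
          classify_growth_dependence(
            filtered, alpha = config$alpha %||% 0.05,
            min_samples = config$min_samples %||% 3,
            p_adjust = config$p_adjust %||% "none")
        })
        manifest <- st$manifest
        calls <- st$value
        if (!is.null(calls)) {
          manifest$stages$classify <- c(manifest$stages$classify,
                                        as.list(attr(calls, "counts")))
          results$calls <- calls
          emit(calls, "dependence_calls.tsv")
          st <- run_stage(manifest, "cluster", {
            dep_ids <- calls$protein_id[!is.na(calls$dependent) & calls$dependent]
            dep_im <- im_subset(filtered,
                                which(filtered$proteins$protein_id %in% dep_ids))
            cluster_profiles(dep_im, k = config$k)
          })
          manifest <- st$manifest
          if (!is.null(st$value)) {
            results$clusters <- st$value
            manifest$stages$cluster$k <- st$value$k
            emit(tidy(st$value), "clusters.tsv")
          }
          if (!is.null(config$annotations)) {
            st <- run_stage(manifest, "enrich", {
              slim <- map_go_slim(as_table(config$annotations$annotations),
                                  as_table(config$annotations$slim))
              enrich_go_slim(calls, slim, alpha = config$alpha %||% 0.05)
            })
            manifest <- st$manifest
            if (!is.null(st$value)) {
              results$enrichment <- st$value
              emit(st$value, "enrichment.tsv")
            }
          }
          if (!is.null(config$calibration)) {
            st <- run_stage(manifest, "quantify", {
              spec <- do.call(calibration_spec, config$calibration[
                setdiff(names(config$calibration), "complex_library")])
              copies <- calibrate_absolute(normalize_ibaq(filtered, spec), spec)
              out <- list(copies = copies)
              if (!is.null(config$calibration$complex_library)) {
                lib <- config$calibration$complex_library
                if (is.character(lib)) lib <- read_complex_library(lib)
                out$complexes <- complex_abundance_table(copies, lib)
              }
              out
            })
            manifest <- st$manifest
            if (!is.null(st$value)) {
              results$quant <- st$value
              emit(st$value$copies, "copies_per_cell.tsv")
              if (!is.null(st$value$complexes)) {
                emit(st$value$complexes, "complex_abundance.tsv")
              }
            }
          }
        }
      }
    }
  }

  # ---- model branch ----
  if (!is.null(config$model)) {
    mc <- config$model
    params <- mc$params %||% model_parameters()
    if (!is.null(mc$observations)) {
      st <- run_stage(manifest, "fit", {
        obs <- if (is.character(mc$observations)) {
          read_growth_observations(mc$observations)
        } else {
          mc$observations
        }
        grid <- mc$grid %||% fit_grid()
        grid_fit(obs, grid, params)
      })
      manifest <- st$manifest
      if (!is.null(st$value)) {
        results$fit <- st$value
        params <- st$value$params_best
        manifest$stages$fit$best <- as.list(st$value$best)
        emit(tidy(st$value), "fit_grid.tsv")
      }
    }
    if (!is.null(mc$light)) {
      st <- run_stage(manifest, "light_response", {
        light_response(params, mc$light)
      })
      manifest <- st$manifest
      if (!is.null(st$value)) {
        results$light_response <- st$value
        emit(as_tibble(st$value), "light_response.tsv")
      }
    }
    if (!is.null(mc$constrained)) {
      st <- run_stage(manifest, "constrained", {
        purrr::map(mc$constrained, function(cs) {
          purrr::map(mc$light %||% 440, function(ii) {
            tidy(constrained_growth(params, ii, class_id = cs$class_id,
                                    phi_Z = cs$phi_Z)) |>
              dplyr::mutate(class_id = cs$class_id, phi_Z = cs$phi_Z)
          }) |> dplyr::bind_rows()
        }) |> dplyr::bind_rows()
      })
      manifest <- st$manifest
      if (!is.null(st$value)) {
        results$constrained <- st$value
        emit(st$value, "constrained_growth.tsv")
      }
    }
  }

  results$manifest <- manifest
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(results)
}
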