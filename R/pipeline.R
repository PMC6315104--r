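# Configuration-driven orchestration: simulate -> features -> quantify ->
# timing -> report. One top-level seed; each stage draws from its own
# substream (stage name hashed into the seed) so adding a stage never
# perturbs earlier stages.

config_schema <- function() {
  list(
    seed = NULL, out_dir = NULL, generation_time_min = NULL,
    simulate = list(
      n_cells = NULL, length_at_birth_um = NULL, length_at_division_um = NULL,
      width_um = NULL, loci = NULL, ring = NULL, n_quantify = NULL,
      write_images = NULL,
      genome = list(length_bp = NULL, ori_pos = NULL, ter_pos = NULL,
                    skew_strength = NULL, replicon_id = NULL),
      image = list(pixel_size_um = NULL, psf_sigma_um = NULL,
                   background_level = NULL, noise_sd = NULL,
                   cell_intensity = NULL, z_step_um = NULL, n_z = NULL)
    ),
    features = list(window_bp = NULL, min_palindrome = NULL,
                    max_mismatch = NULL, consensus = NULL, kops = NULL,
                    circular = NULL, ori_window_bp = NULL),
    quantify = list(max_foci = NULL, ring_k = NULL, coloc_threshold_um = NULL),
    timing = list(scheme = NULL, polar_zone = NULL, midcell_zone = NULL)
  )
}

#' Default pipeline configuration
#'
#' A pure-simulation demonstration setup: one 100-kb skewed replicon with a
#' planted parS-like palindrome near the origin and oppositely stranded
#' KOPS motifs on the two replichores, and a two-locus cell population
#' (sub-polar early-duplicating channel, quarter-cell later-duplicating
#' channel) with a septal ring program.
#'
#' @param n_cells population size.
#' @param seed top-level seed.
#' @return nested configuration list accepted by [run_pipeline()].
#' @export
default_config <- function(n_cells = 2000, seed = 1L) {
  list(
    seed = as.integer(seed),
    out_dir = NULL,
    generation_time_min = 150,
    simulate = list(
      n_cells = n_cells,
      length_at_birth_um = 1.7,
      length_at_division_um = 3.4,
      width_um = 1.0,
      loci = list(
        list(name = "OriC1", duplication_age = 0.19,
             pre_positions = 0.8, post_positions = c(0.15, 0.85),
             position_noise_sd = 0.03),
        list(name = "OriC2", duplication_age = 0.28,
             pre_positions = 0.5, post_positions = c(0.30, 0.70),
             position_noise_sd = 0.03)
      ),
      ring = list(onset_age = 0.6, plateau_um = 0.6,
                  constriction_length_um = 3.0, final_um = 0.1,
                  position = 0.5),
      n_quantify = 200,
      write_images = 0,
      genome = list(length_bp = 100000, ori_pos = 25000, ter_pos = 75000,
                    skew_strength = 0.15, replicon_id = "C2like"),
      image = list(pixel_size_um = 0.064, psf_sigma_um = 0.1,
                   background_level = 100, noise_sd = 5,
                   cell_intensity = 40, z_step_um = 0.125, n_z = 12)
    ),
    features = list(window_bp = 1, min_palindrome = 14, max_mismatch = 2,
                    consensus = "GTTNNNNCGNNNNAAC", kops = "GGNAGGG",
                    circular = TRUE, ori_window_bp = 10000),
    quantify = list(max_foci = 2, ring_k = 1.5, coloc_threshold_um = 0.25),
    timing = list(scheme = NULL, polar_zone = 0.2, midcell_zone = 0.15)
  )
}

#' Validate a pipeline configuration
#'
#' Checks every key (recursively) against the known schema; unknown keys
#' are rejected by name with a condition of class `config_error`.
#'
#' @param config nested configuration list.
#' @return the config, invisibly, if valid.
#' @export
validate_config <- function(config) {
  check <- function(cfg, schema, path) {
    unknown <- setdiff(names(cfg), names(schema))
    if (length(unknown)) {
      stop(structure(class = c("config_error", "error", "condition"),
                     list(message = sprintf("unknown config key(s): %s",
                                            paste(paste0(path, unknown),
                                                  collapse = ", ")),
                          call = NULL)))
    }
    for (k in names(cfg)) {
      if (is.list(schema[[k]]) && length(schema[[k]]) &&
          k %in% c("simulate", "features", "quantify", "timing", "genome",
                   "image")) {
        check(cfg[[k]], schema[[k]], paste0(path, k, "."))
      }
    }
  }
  check(config, config_schema(), "")
  invisible(config)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return validated configuration list, merged over [default_config()].
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(cfg)
  merged <- modifyList(default_config(), cfg)
  validate_config(merged)
  merged
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes `simulate` (genome, population, rendered frames and ring
#' stacks) -> `features` (skew profile, ori/ter, palindromes, consensus and
#' KOPS hits, strand bias, replicon-unique filter) -> `quantify`
#' (segmentation, focus/ring detection, per-cell table, demograph) ->
#' `timing` (per-locus duplication estimates, segregation report,
#' constriction fit) -> `report` (JSON/CSV outputs plus a run manifest
#' with input digests). Re-running with an identical config reproduces
#' byte-identical outputs.
#'
#' @param config configuration list (see [default_config()]); validated
#'   before any stage runs.
#' @param out_dir output directory (created); overrides `config$out_dir`.
#' @return the run manifest, invisibly (class `pipeline_manifest`), with
#'   stage results attached as attribute `"state"`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  validate_config(config)
  out_dir <- out_dir %||% config$out_dir %||% tempfile("chromochoreo_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "chromochoreo",
                   version = as.character(utils::packageVersion("chromochoreo")),
                   seed = config$seed, out_dir = out_dir,
                   stages = list())
  state <- list(config = config)
  for (stage in c("simulate", "features", "quantify", "timing", "report")) {
    fn <- get(paste0("stage_", stage), mode = "function")
    res <- tryCatch(fn(config, state, out_dir), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[stage]] <- list(status = "failed",
                                       message = conditionMessage(res))
      manifest$status <- "failed"
      break
    }
    state <- res$state
    manifest$stages[[stage]] <- list(status = "ok", outputs = res$outputs)
  }
  if (is.null(manifest$status)) manifest$status <- "ok"
  all_outputs <- unlist(lapply(manifest$stages, `[[`, "outputs"))
  if (length(all_outputs)) {
    digs <- tools::md5sum(all_outputs)
    manifest$digests <- as.list(stats::setNames(unname(digs),
                                                basename(all_outputs)))
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  out <- structure(manifest, class = "pipeline_manifest")
  attr(out, "state") <- state
  invisible(out)
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat(sprintf("<pipeline_manifest> seed %d, status %s\n", x$seed, x$status))
  for (s in names(x$stages)) {
    cat(sprintf("  %-9s %s\n", s, x$stages[[s]]$status))
  }
  cat(sprintf("  outputs in %s\n", x$out_dir))
  invisible(x)
}

stage_simulate <- function(config, state, out_dir) {
  sc <- config$simulate
  gspec <- genome_spec(
    length_bp = sc$genome$length_bp, ori_pos = sc$genome$ori_pos,
    ter_pos = sc$genome$ter_pos, skew_strength = sc$genome$skew_strength,
    planted_motifs = planted_demo_motifs(sc$genome),
    replicon_id = sc$genome$replicon_id,
    seed = stage_seed(config$seed, "simulate.genome"))
  genome <- generate_skewed_genome(gspec)
  loci <- lapply(sc$loci, function(l) {
    do.call(locus_program, l)
  })
  pspec <- population_spec(
    n_cells = sc$n_cells, generation_time_min = config$generation_time_min,
    length_at_birth_um = sc$length_at_birth_um,
    length_at_division_um = sc$length_at_division_um,
    width_um = sc$width_um, loci = loci, ring_program = sc$ring,
    seed = stage_seed(config$seed, "simulate.population"))
  pop <- generate_population(pspec)
  ispec <- do.call(image_spec, c(sc$image, list(cell_width_um = sc$width_um)))
  fasta <- file.path(out_dir, "genome.fasta")
  sq <- stats::setNames(list(as.character(genome)), gspec$replicon_id)
  write_fasta(sq, fasta)
  truth_csv <- file.path(out_dir, "cells_truth.csv")
  write.csv(as.data.frame(pop), truth_csv, row.names = FALSE)
  truth_bed <- file.path(out_dir, "features_truth.bed")
  planted <- gspec$planted_motifs
  th <- data.frame(replicon_id = gspec$replicon_id,
                   start = vapply(planted, function(m) as.integer(m$position),
                                  integer(1)),
                   end = vapply(planted, function(m)
                     as.integer(m$position + nchar(m$sequence) - 1L),
                     integer(1)),
                   strand = vapply(planted, function(m) m$strand %||% "+", ""),
                   kind = vapply(planted, function(m) m$kind %||% "motif", ""),
                   mismatches = 0L)
  write_features_bed(th, truth_bed, L = gspec$length_bp)
  outputs <- c(genome_fasta = fasta, cells_truth = truth_csv,
               features_truth = truth_bed)
  if ((sc$write_images %||% 0) > 0) {
    n_img <- min(sc$write_images, length(pop$cells))
    frames <- lapply(seq_len(n_img), function(i) {
      render_cell_image(pop$cells[[i]], ispec,
                        channel = names(pop$cells[[i]]$foci)[1],
                        seed = stage_seed(config$seed,
                                          paste0("simulate.image.", i)))$image
    })
    tif <- file.path(out_dir, "sample_frames.tiff")
    write_stack_tiff(frames, tif)
    outputs <- c(outputs, sample_frames = tif)
  }
  state$genome <- genome
  state$genome_spec <- gspec
  state$population <- pop
  state$image_spec <- ispec
  list(state = state, outputs = outputs)
}

# parS-like perfect palindrome near ori plus KOPS motifs pointing at ter on
# each replichore (plus strand on arc1, minus on arc2)
planted_demo_motifs <- function(g) {
  L <- g$length_bp; ori <- g$ori_pos; ter <- g$ter_pos
  pal <- "GTTACCGCGGTAAC"  # 14-bp perfect reverse-complement palindrome
  kops <- "GGCAGGG"
  fit <- function(pos, len) if (pos + len - 1 > L) L - len + 1 else pos
  arc1 <- function(f) fit((((ori - 1) + round(f * ((ter - ori) %% L))) %% L) + 1,
                          7L)
  arc2 <- function(f) fit((((ter - 1) + round(f * ((ori - ter) %% L))) %% L) + 1,
                          7L)
  motifs <- list(list(sequence = pal, position = arc1(0.02), strand = "+",
                      kind = "parS"))
  for (f in seq(0.1, 0.9, by = 0.1)) {
    motifs <- c(motifs,
                list(list(sequence = kops, position = arc1(f), strand = "+",
                          kind = "kops"),
                     list(sequence = kops, position = arc2(f), strand = "-",
                          kind = "kops")))
  }
  motifs
}

stage_features <- function(config, state, out_dir) {
  fc <- config$features
  seqs <- if (!is.null(state$genome)) {
    stats::setNames(list(as.character(state$genome)),
                    state$genome_spec$replicon_id)
  } else {
    as.list(read_fasta(file.path(out_dir, "genome.fasta")))
  }
  outputs <- c()
  feats <- list()
  for (id in names(seqs)) {
    s <- seqs[[id]]
    prof <- cumulative_gc_skew(s, window_bp = fc$window_bp, replicon_id = id)
    ot <- locate_ori_ter(prof)
    tsv <- file.path(out_dir, paste0("skew_", id, ".tsv"))
    write_skew_tsv(prof, tsv)
    pal <- find_palindromes(s, min_len = fc$min_palindrome,
                            max_mismatch = fc$max_mismatch,
                            circular = isTRUE(fc$circular), replicon_id = id)
    cons <- match_consensus(s, fc$consensus, both_strands = TRUE,
                            circular = isTRUE(fc$circular),
                            kind = "consensus", replicon_id = id)
    kops <- match_consensus(s, fc$kops, both_strands = TRUE,
                            circular = isTRUE(fc$circular),
                            kind = "kops", replicon_id = id)
    bias <- if (!ot$no_extremum) {
      kops_strand_bias(kops, ori = ot$ori, ter = ot$ter, L = nchar(s))
    } else NULL
    uniq <- if (!ot$no_extremum) {
      filter_replicon_unique(pal, other_replicons = seqs[names(seqs) != id],
                             ori = ot$ori, L = nchar(s),
                             ori_window_bp = fc$ori_window_bp)
    } else pal
    hits <- rbind(pal[, c("replicon_id", "start", "end", "strand", "kind",
                          "mismatches")],
                  cons[, c("replicon_id", "start", "end", "strand", "kind",
                           "mismatches")],
                  kops[, c("replicon_id", "start", "end", "strand", "kind",
                           "mismatches")])
    bed <- file.path(out_dir, paste0("features_", id, ".bed"))
    gff <- file.path(out_dir, paste0("features_", id, ".gff3"))
    csv <- file.path(out_dir, paste0("features_", id, ".csv"))
    write_features_bed(hits, bed, L = nchar(s))
    write_features_gff3(hits, gff, L = nchar(s))
    write.csv(hits, csv, row.names = FALSE)
    outputs <- c(outputs, stats::setNames(c(tsv, bed, gff, csv),
                                          paste0(c("skew_", "bed_", "gff_",
                                                   "csv_"), id)))
    feats[[id]] <- list(profile = prof, ori_ter = ot, palindromes = pal,
                        consensus = cons, kops = kops, kops_bias = bias,
                        unique_candidates = uniq)
  }
  state$features <- feats
  list(state = state, outputs = outputs)
}

stage_quantify <- function(config, state, out_dir) {
  qc <- config$quantify
  sc <- config$simulate
  pop <- state$population
  ispec <- state$image_spec
  n_q <- min(sc$n_quantify %||% length(pop$cells), length(pop$cells))
  channels <- vapply(pop$spec$loci, `[[`, "", "name")
  measured <- list()
  profiles <- list()
  lengths <- numeric()
  for (i in seq_len(n_q)) {
    cell <- pop$cells[[i]]
    frames <- lapply(channels, function(ch) {
      render_cell_image(cell, ispec, channel = ch,
                        seed = stage_seed(config$seed,
                                          paste0("quantify.", i, ".", ch)))$image
    })
    names(frames) <- channels
    obs <- quantify_frames(frames, pixel_size_um = ispec$pixel_size_um,
                           max_foci = qc$max_foci, ring_channel = channels[1],
                           ring_k = qc$ring_k, cell_id = cell$cell_id)
    if (is.null(obs)) next
    # ring diameter round-trip from a rendered z-stack of the true ring
    if (!is.null(cell$ring)) {
      stk <- render_ring_zstack(cell$ring$diameter_um, ispec,
                                seed = stage_seed(config$seed,
                                                  paste0("quantify.ring.", i)))
      m <- ring_diameter_from_stack(stk)
      if (is.null(obs$ring)) obs$ring <- list(frac = cell$ring$frac)
      obs$ring$diameter_um <- m$diameter_um
    }
    measured[[length(measured) + 1L]] <- obs
    mask_frame <- frames[[1]]
    reg <- segment_cells(mask_frame, pixel_size_um = ispec$pixel_size_um)
    if (length(reg) == 1) {
      profiles[[length(profiles) + 1L]] <- axial_profile(mask_frame,
                                                         reg[[1]]$mask)
      lengths <- c(lengths, reg[[1]]$length_um)
    }
  }
  if (!length(measured)) stopf("quantify: no cells could be measured")
  tab <- cells_to_table(measured)
  csv <- file.path(out_dir, "cells_measured.csv")
  write.csv(tab, csv, row.names = FALSE)
  dg <- demograph(profiles, lengths)
  dg_csv <- file.path(out_dir, "demograph.csv")
  write_demograph_csv(dg, dg_csv)
  state$measured <- measured
  state$measured_table <- tab
  state$demograph <- dg
  list(state = state,
       outputs = c(cells_measured = csv, demograph = dg_csv))
}

stage_timing <- function(config, state, out_dir) {
  tc <- config$timing
  measured <- state$measured
  channels <- vapply(state$population$spec$loci, `[[`, "", "name")
  estimates <- lapply(channels, function(ch) {
    estimate_duplication(measured, channel = ch,
                         T_min = config$generation_time_min, locus = ch)
  })
  report <- segregation_report(estimates)
  tab <- state$measured_table
  cf <- NULL
  pairs_ok <- !is.na(tab$ring_diameter_um)
  if (sum(pairs_ok) >= 6) {
    cf <- constriction_phases(tab$length_um[pairs_ok],
                              tab$ring_diameter_um[pairs_ok])
  }
  loc <- if (!is.null(tc$scheme)) {
    localization_table(measured, scheme = tc$scheme,
                       polar = tc$polar_zone, midcell = tc$midcell_zone)
  } else NULL
  timing_csv <- file.path(out_dir, "timing.csv")
  write.csv(report$table, timing_csv, row.names = FALSE)
  state$estimates <- estimates
  state$segregation <- report
  state$constriction <- cf
  state$localization <- loc
  list(state = state, outputs = c(timing = timing_csv))
}

stage_report <- function(config, state, out_dir) {
  rep <- list(
    seed = config$seed,
    generation_time_min = config$generation_time_min,
    loci = state$segregation$table,
    intervals = state$segregation$intervals,
    genome = lapply(state$features, function(f) {
      list(ori = f$ori_ter$ori, ter = f$ori_ter$ter,
           n_palindromes = nrow(f$palindromes),
           n_consensus = nrow(f$consensus),
           n_kops = nrow(f$kops),
           kops_verdict = if (!is.null(f$kops_bias)) f$kops_bias$verdict
                          else NA,
           n_unique_candidates = nrow(f$unique_candidates))
    }),
    constriction = if (!is.null(state$constriction)) {
      list(changepoint_um = state$constriction$changepoint_um,
           plateau_um = state$constriction$plateau_um,
           slope = state$constriction$slope,
           degenerate = state$constriction$degenerate)
    } else NULL,
    localization = state$localization,
    n_measured = length(state$measured)
  )
  path <- file.path(out_dir, "report.json")
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  list(state = state, outputs = c(report = path))
}
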