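# Run configuration with validated defaults, flat key = value config files,
# and the subcommand dispatcher behind the command-line wrapper.

#' Validated run configuration
#'
#' Collects every tunable of the pipeline with its default: surface density
#' 5 pts/A^2 and probe 1.4 A; CA-CA contact cutoff 8 A; occurrence
#' threshold 0.25; Zernike order 20 on a 64-pixel disk grid; patch radius
#' 9 A; cost weights A = 10, B = 0.04, C = 32.1, D = 0.5 with beta = 1;
#' 10 runs of 6000 steps; candidate filter at <= 5 mutations / top 100.
#'
#' @param ... Named overrides of the defaults.
#' @return A validated `pepmc_config` list.
#' @export
pepmc_config <- function(...) {
  cfg <- list(density = 5, probe_radius = 1.4, contact_cutoff = 8,
              occurrence_threshold = 0.25, order = 20, grid_size = 64,
              patch_radius = 9, A = 10, B = 0.04, C = 32.1, D = 0.5,
              beta = 1, n_steps = 6000, n_runs = 10, max_mutations = 5,
              top_k = 100, seed = 1, dielectric = 1,
              penalty = "signed_quadratic", combining = "charmm",
              alphabet = paste(.default_alphabet, collapse = ""))
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  num <- function(x) suppressWarnings(as.numeric(x))
  for (key in c("density", "probe_radius", "contact_cutoff",
                "occurrence_threshold", "order", "grid_size", "patch_radius",
                "A", "B", "C", "D", "beta", "n_steps", "n_runs",
                "max_mutations", "top_k", "seed", "dielectric"))
    cfg[[key]] <- num(cfg[[key]])
  checks <- list(
    density = cfg$density > 0, probe_radius = cfg$probe_radius >= 0,
    contact_cutoff = cfg$contact_cutoff > 0,
    occurrence_threshold = cfg$occurrence_threshold >= 0 &&
      cfg$occurrence_threshold < 1,
    order = cfg$order >= 0, grid_size = cfg$grid_size >= 8,
    patch_radius = cfg$patch_radius > 0, beta = cfg$beta > 0,
    n_steps = cfg$n_steps >= 1, n_runs = cfg$n_runs >= 1,
    max_mutations = cfg$max_mutations >= 0, top_k = cfg$top_k >= 1,
    dielectric = cfg$dielectric > 0,
    penalty = cfg$penalty %in% c("signed_quadratic", "cubic"),
    combining = cfg$combining %in% c("charmm", "literal"),
    alphabet = all(strsplit(cfg$alphabet, "")[[1]] %in% names(.aa_three)))
  bad <- names(checks)[!vapply(checks, isTRUE, logical(1))]
  if (length(bad))
    stop("invalid config value(s) for: ", paste(bad, collapse = ", "))
  structure(cfg, class = "pepmc_config")
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment.  Values override
#' the package defaults; command-line flags override both.
#'
#' @param path Config file path.
#' @return A `pepmc_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  over <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  do.call(pepmc_config, over)
}

#' @keywords internal
.parse_cli_args <- function(args) {
  out <- list(positional = character(0), flags = list())
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- gsub("-", "_", sub("^--", "", a))
      if (i < length(args) && !startsWith(args[i + 1], "--")) {
        out$flags[[key]] <- args[i + 1]; i <- i + 2
      } else {
        out$flags[[key]] <- TRUE; i <- i + 1
      }
    } else {
      out$positional <- c(out$positional, a); i <- i + 1
    }
  }
  out
}

#' @keywords internal
.write_provenance <- function(outdir, cfg, extra = list()) {
  cfg_path <- file.path(outdir, "config.json")
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE,
                       digits = NA)
  prov <- c(list(package = "pepmc",
                 version = as.character(utils::packageVersion("pepmc")),
                 seed = cfg$seed,
                 config_md5 = unname(tools::md5sum(cfg_path))), extra)
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Run a pipeline stage as a subcommand
#'
#' Entry point behind the `pepmc` command-line wrapper
#' (`inst/cli/pepmc.R`).  Subcommands: `surface` (SAS cloud + optional
#' patch descriptors), `zernike` (expand a disk-image CSV), `fixtures`
#' (write generator output as PDB), `analyze-interface` (contact profile +
#' extension statistics), `extract-peptide` (profile + segment report),
#' `optimize` (Monte Carlo runs), `filter-candidates`, `msa-freqs`.
#' Artifacts are written to `--out` together with a provenance JSON
#' (package version, seed, config hash).
#'
#' @param name Subcommand name.
#' @param args Character vector of remaining command-line arguments.
#' @param config Base `pepmc_config` (flags override it).
#' @return Exit status, invisibly (0 on success).
#' @export
run_subcommand <- function(name, args = character(), config = pepmc_config()) {
  known <- c("surface", "zernike", "analyze-interface", "extract-peptide",
             "optimize", "filter-candidates", "msa-freqs", "fixtures")
  if (!name %in% known) stop("unknown subcommand: ", name)
  parsed <- .parse_cli_args(args)
  flags <- parsed$flags
  outdir <- flags$out %||% "pepmc_out"
  flags$out <- NULL
  input <- flags$input
  flags$input <- NULL
  cfg_keys <- intersect(names(flags), names(config))
  config <- do.call(pepmc_config, utils::modifyList(unclass(config),
                                                    flags[cfg_keys]))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  need_input <- function() {
    if (is.null(input)) stop("missing required --input for '", name, "'")
    if (!file.exists(input)) stop("input file not found: ", input)
    input
  }
  switch(name,
    "surface" = {
      st <- read_structure(need_input())
      cloud <- compute_sas_points(st, config$density, config$probe_radius)
      utils::write.csv(data.frame(cloud$points, cloud$normals),
                       file.path(outdir, "surface_points.csv"),
                       row.names = FALSE)
    },
    "zernike" = {
      # expand a disk image stored as a square CSV of pixel values
      # (empty/NA cells are outside the disk)
      m <- as.matrix(utils::read.csv(need_input(), header = FALSE))
      if (nrow(m) != ncol(m)) stop("disk-image CSV must be square")
      g <- nrow(m)
      centers <- (seq_len(g) - 0.5) * (2 / g) - 1
      in_disk <- outer(centers^2, centers^2, "+") <= 1
      img <- new_disk_image(ifelse(in_disk, m, NA_real_), in_disk,
                            matrix(as.integer(in_disk & !is.na(m)), g, g), g)
      ex <- zernike_expand(img, config$order)
      write_invariants_csv(list(image = zernike_invariants(ex)),
                           file.path(outdir, "invariants.csv"))
    },
    "fixtures" = {
      set.seed(config$seed)
      dimer <- make_toy_dimer(n_res = as.integer(flags$n_res %||% 8),
                              separation = as.numeric(flags$separation %||% 6))
      write_structure(dimer, file.path(outdir, "toy_dimer.pdb"))
      occ <- rep(0.5, 8)
      traj <- make_synthetic_trajectory(dimer, occ, n_frames = 10,
                                        seed = config$seed)
      write_structure(traj, file.path(outdir, "toy_trajectory.pdb"))
    },
    "analyze-interface" = ,
    "extract-peptide" = {
      traj <- read_trajectory(need_input())
      prof <- contact_occurrence(traj, "A", "B", config$contact_cutoff)
      write_contact_profile(prof, file.path(outdir, "contact_profile.tsv"))
      if (name == "extract-peptide") {
        seg <- select_peptide_segment(prof, config$occurrence_threshold)
        jsonlite::write_json(seg[c("start", "end", "length",
                                   "mean_occurrence")],
                             file.path(outdir, "segment.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    },
    "optimize" = {
      scorer <- if (isTRUE(flags$stub_scorer)) make_stub_scorer()
      else {
        st <- assign_parameters(read_structure(need_input()))
        make_surface_scorer(subset_chains(st, "B"), subset_chains(st, "A"),
                            patch_radius = config$patch_radius,
                            order = config$order,
                            grid_size = config$grid_size,
                            density = config$density,
                            probe_radius = config$probe_radius,
                            contact_cutoff = config$contact_cutoff,
                            dielectric = config$dielectric)
      }
      peptide <- if (isTRUE(flags$stub_scorer)) {
        assign_parameters(subset_chains(make_toy_dimer(), "A"))
      } else assign_parameters(subset_chains(read_structure(input), "A"))
      w <- cost_weights(config$A, config$B, config$C, config$D, config$beta)
      runs <- lapply(seq_len(config$n_runs), function(k)
        run_chain(peptide, "A", scorer, w, n_steps = config$n_steps,
                  seed = config$seed + k - 1,
                  alphabet = strsplit(config$alphabet, "")[[1]],
                  penalty = config$penalty))
      for (k in seq_along(runs))
        utils::write.csv(runs[[k]]$steps,
                         file.path(outdir, sprintf("run_%02d_steps.csv", k)),
                         row.names = FALSE)
      cand <- filter_candidates(runs, w, config$max_mutations, config$top_k)
      utils::write.table(cand, file.path(outdir, "candidates.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      writeLines(paste0(">candidate_", seq_len(nrow(cand)), "\n",
                        cand$sequence),
                 file.path(outdir, "candidates.fasta"))
    },
    "filter-candidates" = {
      # re-filter a pooled state log (TSV with sequence, M, Z_d, E_c, H_d)
      pool <- utils::read.delim(need_input())
      w <- cost_weights(config$A, config$B, config$C, config$D, config$beta)
      fake_run <- structure(list(accepted = pool), class = "mc_run")
      cand <- filter_candidates(list(fake_run), w, config$max_mutations,
                                config$top_k)
      utils::write.table(cand, file.path(outdir, "candidates.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    },
    "msa-freqs" = {
      ref <- flags$reference
      if (is.null(ref)) stop("missing required --reference for msa-freqs")
      pos <- as.integer(strsplit(flags$positions %||% "1", ",")[[1]])
      fr <- msa_position_frequencies(need_input(), pos, ref)
      jsonlite::write_json(fr, file.path(outdir, "frequencies.json"),
                           digits = NA)
    },
    stop("unknown subcommand: ", name)
  )
  .write_provenance(outdir, config, list(subcommand = name))
  invisible(0L)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
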