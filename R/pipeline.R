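#' Reproducible run configuration
#'
#' A run is fully determined by its configuration and master seed; every
#' stage draws from a named substream derived from the master seed, so
#' stages can be re-run independently.
#'
#' @param experiment 1 (enforced end-expiratory variability) or 2 (natural
#'   variability, breath-hold vs navigator-gated).
#' @param phantom a [phantom_config()].
#' @param respiratory a [respiratory_config()].
#' @param recon a [recon_params()].
#' @param n_subjects simulated subjects (defaults: 16 for experiment 1 --
#'   nine healthy plus seven patients analyzed together -- and 20 for
#'   experiment 2).
#' @param n_pairs basal/apical pairs per protocol (experiment 2).
#' @param seed master integer seed.
#' @param output_dir optional directory for CSV/JSON/log outputs.
#' @param loa_flavor see [analyze_experiment2()].
#' @return list of class `run_config`.
#' @export
run_config <- function(experiment = 1,
                       phantom = phantom_config(),
                       respiratory = respiratory_config(),
                       recon = recon_params(),
                       n_subjects = if (experiment == 1) 16L else 20L,
                       n_pairs = 10L,
                       seed = 1L,
                       output_dir = NULL,
                       loa_flavor = "consecutive") {
  stopifnot(experiment %in% c(1, 2), n_subjects >= 1, n_pairs >= 2)
  structure(list(
    experiment = as.integer(experiment),
    phantom = phantom,
    respiratory = respiratory,
    recon = recon,
    n_subjects = as.integer(n_subjects),
    n_pairs = as.integer(n_pairs),
    seed = as.integer(seed),
    output_dir = output_dir,
    loa_flavor = loa_flavor
  ), class = "run_config")
}

#' Quantify one experiment-1 session
#'
#' Reconstructs all eight acquisitions, computes peak twist angles, the nine
#' permutation torsions and the two middle-window reference torsions, using
#' plane metadata only for distances.
#'
#' @param session a [simulate_experiment1()] session.
#' @param params a [recon_params()].
#' @return list with `nine`, `ref_pair`, `scout_range`, `d_cm` and the
#'   per-acquisition `twists` table.
#' @export
quantify_experiment1 <- function(session, params = recon_params()) {
  stopifnot(inherits(session, "dense_session"), session$experiment == 1L)
  twists <- lapply(session$acquisitions, twist_from_acquisition, params = params)
  basal <- twists[c("min.basal", "mid.basal", "max.basal")]
  apical <- twists[c("min.apical", "mid.apical", "max.apical")]
  nine <- nine_permutations(basal, apical)
  ref_pair <- c(
    torsion_curve(twists[["mid.basal"]], twists[["mid.apical"]])$peak_torsion,
    torsion_curve(twists[["mid_repeat.basal"]], twists[["mid_repeat.apical"]])$peak_torsion
  )
  tw_tab <- data.frame(
    subject = session$subject_id,
    window = vapply(session$acquisitions, function(a) a$window, character(1)),
    slice = vapply(session$acquisitions, function(a) a$slice_label, character(1)),
    peak_twist_deg = vapply(twists, function(t) {
      t$angles_deg[which.max(abs(t$angles_deg))]
    }, numeric(1)),
    row.names = NULL
  )
  list(nine = nine, ref_pair = ref_pair,
       scout_range = diff(range(session$scout_positions)),
       d_cm = slice_distance(twists[["mid.basal"]], twists[["mid.apical"]]),
       twists = tw_tab)
}

#' Quantify one experiment-2 session
#'
#' Reconstructs both protocols' interleaved series and derives the `2n`
#' consecutive-pairing torsion measurements per protocol.
#'
#' @param session a [simulate_experiment2()] session.
#' @param params a [recon_params()].
#' @return list with `torsions` (data.frame: subject, protocol, order,
#'   basal, apical, d_cm, peak_torsion) and `position_sd` (data.frame:
#'   subject, protocol, position_sd from the navigator log).
#' @export
quantify_experiment2 <- function(session, params = recon_params()) {
  stopifnot(inherits(session, "dense_session"), session$experiment == 2L)
  out <- lapply(names(session$protocols), function(proto) {
    twists <- lapply(session$protocols[[proto]], twist_from_acquisition,
                     params = params)
    pr <- pair_torsions(twists)
    data.frame(subject = session$subject_id, protocol = proto,
               order = seq_len(nrow(pr)), basal = pr$basal, apical = pr$apical,
               d_cm = slice_distance(twists[[1]], twists[[2]]),
               peak_torsion = pr$peak_torsion, row.names = NULL)
  })
  pos <- data.frame(
    subject = session$subject_id,
    protocol = names(session$navigator_log),
    position_sd = vapply(session$navigator_log, stats::sd, numeric(1)),
    row.names = NULL
  )
  list(torsions = do.call(rbind, out), position_sd = pos)
}

#' Run a full simulated experiment
#'
#' Simulates every subject, reconstructs and quantifies torsion, runs the
#' experiment's variability analysis, and derives the sample-size table from
#' the measured limits of agreement (delta = 10% of the measured mean
#' torsion). If `config$output_dir` is set, writes `torsions.csv`,
#' `report.json`, `samplesize.csv` and `run.log` (with the config hash and
#' seed for provenance).
#'
#' @param config a [run_config()].
#' @return list of class `run_report`: `config`, `config_hash`, `torsions`,
#'   `variability` (a `variability_report`), `sample_size` (data.frame),
#'   `mean_torsion`, `delta`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config$phantom; resp <- config$respiratory
  plan <- plan_slices(cfg)
  hash <- config_hash(config[setdiff(names(config), "output_dir")])
  log_lines <- c(
    sprintf("lvtorsion run: experiment %d", config$experiment),
    sprintf("config hash: %s  seed: %d  subjects: %d",
            hash, config$seed, config$n_subjects),
    sprintf("R %s, lvtorsion %s", getRversion(),
            as.character(utils::packageVersion("lvtorsion")))
  )
  if (config$experiment == 1L) {
    per_subject <- list()
    tor_rows <- list()
    for (i in seq_len(config$n_subjects)) {
      sid <- sprintf("S%02d", i)
      ses <- simulate_experiment1(cfg, resp, plan, subject_id = sid,
                                  seed = derive_seed(config$seed, "subject", i))
      q <- quantify_experiment1(ses, config$recon)
      per_subject[[sid]] <- q
      tor_rows[[sid]] <- data.frame(
        subject = sid,
        protocol = c(rep("enforced", 9), "consistent", "consistent"),
        basal_idx = c(rep(1:3, each = 3), 2L, 4L),
        apical_idx = c(rep(1:3, 3), 2L, 4L),
        d_cm = q$d_cm,
        peak_torsion = c(unname(q$nine), q$ref_pair)
      )
    }
    rep1 <- analyze_experiment1(per_subject)
    torsions <- do.call(rbind, tor_rows)
    # enforced-variability LoA: spread of permutations about each subject's
    # reference center, pooled across subjects
    perm_dev <- unlist(lapply(per_subject, function(s) s$nine - mean(s$ref_pair)))
    loa <- c(enforced = limits_of_agreement(perm_dev),
             consistent = rep1$loa_halfwidth)
    mean_tau <- rep1$mean_torsion
    variability <- rep1
  } else {
    tor_list <- list(); pos_list <- list()
    for (i in seq_len(config$n_subjects)) {
      sid <- sprintf("S%02d", i)
      ses <- simulate_experiment2(cfg, resp, plan, n_pairs = config$n_pairs,
                                  subject_id = sid,
                                  seed = derive_seed(config$seed, "subject", i))
      q <- quantify_experiment2(ses, config$recon)
      tor_list[[sid]] <- q$torsions
      pos_list[[sid]] <- q$position_sd
    }
    torsions <- do.call(rbind, tor_list)
    rownames(torsions) <- NULL
    variability <- analyze_experiment2(torsions, do.call(rbind, pos_list),
                                       loa_flavor = config$loa_flavor)
    loa <- variability$loa_halfwidth
    mean_tau <- variability$mean_torsion
  }
  delta <- 0.10 * mean_tau
  sstab <- sample_size_table(loa, delta)
  report <- structure(list(
    config = config, config_hash = hash,
    torsions = torsions,
    variability = variability,
    sample_size = sstab,
    mean_torsion = mean_tau,
    delta = delta
  ), class = "run_report")
  if (!is.null(config$output_dir)) write_run_report(report, config$output_dir,
                                                    log_lines)
  report
}

# Serialize a run_report to plain-text artifacts.
write_run_report <- function(report, dir, log_lines = character(0)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$torsions, file.path(dir, "torsions.csv"),
                   row.names = FALSE)
  utils::write.csv(report$sample_size, file.path(dir, "samplesize.csv"),
                   row.names = FALSE)
  v <- report$variability
  json <- list(
    experiment = v$experiment,
    config_hash = report$config_hash,
    seed = report$config$seed,
    mean_torsion = report$mean_torsion,
    delta = report$delta,
    sample_size = report$sample_size
  )
  json <- c(json, unclass(v)[setdiff(names(v), "per_subject_wide")])
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  writeLines(c(log_lines, sprintf("written: %s", format(Sys.time()))),
             file.path(dir, "run.log"))
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> experiment %d (hash %s, seed %d)\n",
              x$config$experiment, x$config_hash, x$config$seed))
  cat(sprintf("  mean torsion %.2f deg/cm, delta %.3f deg/cm\n",
              x$mean_torsion, x$delta))
  print(x$variability)
  cat("  sample sizes:\n")
  for (i in seq_len(nrow(x$sample_size)))
    cat(sprintf("    %-12s LoA +/-%.2f -> n = %d\n",
                x$sample_size$condition[i], x$sample_size$loa_halfwidth[i],
                x$sample_size$n[i]))
  invisible(x)
}

#' Summary tables over one or more run reports
#'
#' Produces a mean-and-SD torsion table per protocol and a pooled
#' sample-size table (means of the per-run limits of agreement).
#'
#' @param reports a `run_report` or list of them.
#' @return list with data.frames `torsion_summary` and `sample_size`.
#' @export
generate_report <- function(reports) {
  if (inherits(reports, "run_report")) reports <- list(reports)
  stopifnot(length(reports) >= 1)
  tor <- do.call(rbind, lapply(reports, function(r) {
    agg <- stats::aggregate(peak_torsion ~ protocol, data = r$torsions,
                            FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
    data.frame(experiment = r$config$experiment,
               protocol = agg$protocol,
               mean_torsion = agg$peak_torsion[, "mean"],
               sd_torsion = agg$peak_torsion[, "sd"])
  }))
  prot <- split(tor, list(tor$experiment, tor$protocol), drop = TRUE)
  torsion_summary <- do.call(rbind, lapply(prot, function(df) {
    data.frame(experiment = df$experiment[1], protocol = df$protocol[1],
               mean_torsion = mean(df$mean_torsion),
               sd_torsion = mean(df$sd_torsion))
  }))
  rownames(torsion_summary) <- NULL
  ss <- do.call(rbind, lapply(reports, function(r) {
    cbind(experiment = r$config$experiment, r$sample_size)
  }))
  bycond <- split(ss, list(ss$experiment, ss$condition), drop = TRUE)
  sample_size <- do.call(rbind, lapply(bycond, function(df) {
    loa <- mean(df$loa_halfwidth)
    delta <- mean(vapply(reports, function(r) r$delta, numeric(1)))
    data.frame(experiment = df$experiment[1], condition = df$condition[1],
               loa_halfwidth = loa, n = required_n(loa / 1.96, delta))
  }))
  rownames(sample_size) <- NULL
  list(torsion_summary = torsion_summary, sample_size = sample_size)
}

#' Command-line interface
#'
#' Subcommands: `run-all` (simulate, reconstruct, quantify, analyze, write
#' reports), `samplesize` (the power formula), and `simulate` (write a
#' simulated session to an RDS file). Run via
#' `Rscript -e 'lvtorsion::lvtorsion_cli()' run-all --experiment 1 --seed 1 --out outdir`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status, invisibly.
#' @export
lvtorsion_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1) {
    message("usage: lvtorsion_cli <run-all|simulate|samplesize> [options]")
    return(invisible(1L))
  }
  cmd <- args[1]
  rest <- args[-1]
  if (cmd == "samplesize") {
    opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
      optparse::make_option("--sigma", type = "double"),
      optparse::make_option("--delta", type = "double"),
      optparse::make_option("--alpha", type = "double", default = 0.05),
      optparse::make_option("--power", type = "double", default = 0.90)
    )), args = rest)
    n <- required_n(opts$sigma, opts$delta, opts$alpha, opts$power)
    cat(sprintf("f(%.3g, %.3g) = %.1f; n = %d per group\n",
                opts$alpha, opts$power, factor_f(opts$alpha, opts$power), n))
    return(invisible(0L))
  }
  opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
    optparse::make_option("--experiment", type = "integer", default = 1L),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--subjects", type = "integer", default = NA_integer_),
    optparse::make_option("--out", type = "character", default = "lvtorsion_out")
  )), args = rest)
  if (cmd == "simulate") {
    cfg <- phantom_config(); resp <- respiratory_config()
    ses <- if (opts$experiment == 1L)
      simulate_experiment1(cfg, resp, seed = opts$seed)
    else simulate_experiment2(cfg, resp, seed = opts$seed)
    dir.create(dirname(opts$out), recursive = TRUE, showWarnings = FALSE)
    saveRDS(ses, paste0(sub("\\.rds$", "", opts$out), ".rds"))
    message("session written to ", paste0(sub("\\.rds$", "", opts$out), ".rds"))
    return(invisible(0L))
  }
  if (cmd == "run-all") {
    ns <- if (is.na(opts$subjects)) {
      if (opts$experiment == 1L) 16L else 20L
    } else opts$subjects
    config <- run_config(experiment = opts$experiment, seed = opts$seed,
                         n_subjects = ns, output_dir = opts$out)
    report <- run_experiment(config)
    print(report)
    return(invisible(0L))
  }
  message("unknown subcommand: ", cmd)
  invisible(1L)
}
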