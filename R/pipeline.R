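#' Pipeline configuration
#'
#' End-to-end configuration for [run_pipeline()]. Inputs may be given as
#' file paths (read with [read_genotypes()] / [read_traits()]) or as
#' in-memory objects.
#'
#' @param genotypes a [genotype_matrix()] or path to a genotype file.
#' @param traits a [trait_table()] or path, or `NULL` to skip phenotypes.
#' @param out_dir output directory (created if absent).
#' @param genotype_dialect dialect for a genotype path.
#' @param populations population labels to summarise markers for
#'   (default: the labels present in the data).
#' @param do_pheno,do_marker,do_distance,do_tree,do_structure,do_pcoa
#'   stage toggles.
#' @param tree_method `"nj"` (default, as used for the reference tree) or
#'   `"upgma"`; both trees are written when `"both"`.
#' @param distance_variant chord scaling variant, see [chord_distance()].
#' @param k_range K values for the admixture scan.
#' @param runs,iterations,burnin MCMC settings per K.
#' @param q_threshold clear-membership threshold for group assignment.
#' @param n_axes PCoA axes to export.
#' @param seed base seed, recorded in every output header.
#' @param verbose print stage progress?
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(genotypes, traits = NULL, out_dir = "results",
                            genotype_dialect = "delimited",
                            populations = NULL,
                            do_pheno = TRUE, do_marker = TRUE,
                            do_distance = TRUE, do_tree = TRUE,
                            do_structure = TRUE, do_pcoa = TRUE,
                            tree_method = c("nj", "upgma", "both"),
                            distance_variant = "chord",
                            k_range = 1:5, runs = 4, iterations = 5000,
                            burnin = 1000, q_threshold = 0.6, n_axes = 2,
                            seed = 1, verbose = TRUE) {
  structure(list(genotypes = genotypes, traits = traits, out_dir = out_dir,
                 genotype_dialect = genotype_dialect,
                 populations = populations,
                 do_pheno = do_pheno, do_marker = do_marker,
                 do_distance = do_distance, do_tree = do_tree,
                 do_structure = do_structure, do_pcoa = do_pcoa,
                 tree_method = match.arg(tree_method),
                 distance_variant = distance_variant,
                 k_range = k_range, runs = runs, iterations = iterations,
                 burnin = burnin, q_threshold = q_threshold,
                 n_axes = n_axes, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; `genotypes`/`traits`
#' must be file paths.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$k_range)) cfg$k_range <- do.call(seq, as.list(cfg$k_range))
  do.call(pipeline_config, cfg)
}

## write a CSV with a provenance header line ("# pepperdiv seed=... stage=...")
write_report_csv <- function(df, path, seed, stage, digits = NULL) {
  if (!is.null(digits)) {
    for (nm in names(digits)) {
      cols <- grep(nm, names(df), value = TRUE)
      for (cl in cols)
        if (is.numeric(df[[cl]])) df[[cl]] <- round(df[[cl]], digits[[nm]])
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pepperdiv stage=%s seed=%d", stage, seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

## reporting precision used throughout: indices 2 dp, percentages/CV 1 dp
report_digits <- c("^h$" = 2, "^dh$" = 2, "freq" = 1, "^cv$" = 1,
                   "major_allele_freq" = 2, "gene_diversity" = 2,
                   "heterozygosity" = 2, "^pic$" = 2)

#' Run the full diversity pipeline
#'
#' Executes the enabled stages on one dataset and writes the report
#' bundle: phenotypic diversity tables (rounded as in the reference
#' tables, plus full-precision `*_precise` files), per-population marker
#' summaries, the chord-distance matrix (PHYLIP), NJ/UPGMA Newick trees,
#' per-K Q matrices with the Evanno delta-K table and group membership,
#' PCoA coordinates, and a line-oriented run log with seed and per-stage
#' counts. Reruns with the same config are bit-identical.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, a list of the in-memory stage results plus
#'   `files` (the written paths).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  t0 <- Sys.time()
  logline <- function(...) {
    msg <- paste0(...)
    writeLines(msg, log_con)
    if (cfg$verbose) message(msg)
  }
  logline("pepperdiv pipeline, seed=", cfg$seed)
  stage <- function(name, expr) {
    st <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    logline(sprintf("stage %-10s ok (%.1fs)", name,
                    as.numeric(difftime(Sys.time(), st, units = "secs"))))
    out
  }

  gm <- if (inherits(cfg$genotypes, "genotype_matrix")) cfg$genotypes else
    stage("read", read_genotypes(cfg$genotypes, cfg$genotype_dialect))
  tt <- if (is.null(cfg$traits) || inherits(cfg$traits, "trait_table"))
    cfg$traits else stage("read", read_traits(cfg$traits))
  logline("input: ", nrow(gm$a1), " accessions x ", ncol(gm$a1), " loci",
          if (!is.null(tt)) paste0("; ", ncol(tt$qualitative), "+",
                                   ncol(tt$quantitative), " traits"))
  issues <- validate_dataset(gm, tt)
  logline("validation issues: ", nrow(issues))

  res <- list(gm = gm, tt = tt, issues = issues)
  files <- character(0)
  put <- function(df, name, digits = report_digits) {
    p <- file.path(cfg$out_dir, name)
    write_report_csv(df, p, cfg$seed, sub("\\.csv$", "", name), digits)
    files <<- c(files, p)
  }

  if (cfg$do_pheno && !is.null(tt)) {
    pd <- stage("pheno", pheno_diversity(tt))
    pops <- unique(tt$pop)
    diffs <- if (length(pops) == 2) {
      pick <- function(df, p) df[df$pop == p, , drop = FALSE]
      list(qualitative = compare_populations(pick(pd$qualitative, pops[1]),
                                             pick(pd$qualitative, pops[2])),
           quantitative = compare_populations(pick(pd$quantitative, pops[1]),
                                              pick(pd$quantitative, pops[2])))
    }
    put(pd$qualitative, "pheno_qualitative.csv")
    put(pd$qualitative, "pheno_qualitative_precise.csv", digits = NULL)
    put(pd$quantitative, "pheno_quantitative.csv")
    put(pd$quantitative, "pheno_quantitative_precise.csv", digits = NULL)
    if (!is.null(diffs)) {
      put(diffs$qualitative, "pheno_qualitative_diff.csv")
      put(diffs$quantitative, "pheno_quantitative_diff.csv")
    }
    res$pheno <- pd
    res$pheno_diff <- diffs
  }

  if (cfg$do_marker) {
    pops <- cfg$populations
    if (is.null(pops)) pops <- if (is.null(gm$pop)) list(NULL) else unique(gm$pop)
    marker <- stage("marker", lapply(pops, function(p) summarize_panel(gm, p)))
    names(marker) <- vapply(pops, function(p) if (is.null(p)) "all" else p, "")
    for (nm in names(marker)) {
      tab <- marker[[nm]]$per_locus
      put(tab, paste0("marker_summary_", nm, ".csv"))
      put(tab, paste0("marker_summary_", nm, "_precise.csv"), digits = NULL)
      logline("marker panel ", nm, ": total alleles ",
              marker[[nm]]$total_alleles)
    }
    res$marker <- marker
  }

  dm <- NULL
  if (cfg$do_distance || cfg$do_tree || cfg$do_pcoa) {
    dm <- stage("distance", distance_matrix(gm, variant = cfg$distance_variant))
    p <- file.path(cfg$out_dir, "chord_distances.phy")
    write_phylip(dm, p)
    files <- c(files, p)
    logline(sprintf("distances: min %.3f mean %.3f max %.3f",
                    dm$summary["min"], dm$summary["mean"], dm$summary["max"]))
    res$distances <- dm
  }

  if (cfg$do_tree) {
    methods <- if (cfg$tree_method == "both") c("nj", "upgma") else cfg$tree_method
    for (m in methods) {
      tr <- stage(m, if (m == "nj") nj_tree(dm) else upgma_tree(dm))
      p <- file.path(cfg$out_dir, paste0("tree_", m, ".nwk"))
      write_newick(tr, p)
      files <- c(files, p)
      res[[paste0("tree_", m)]] <- tr
    }
  }

  if (cfg$do_structure) {
    scan <- stage("structure",
                  structure_scan(gm, cfg$k_range, runs = cfg$runs,
                                 iterations = cfg$iterations,
                                 burnin = cfg$burnin, seed = cfg$seed))
    for (k in cfg$k_range) {
      fit <- scan$fits[[as.character(k)]]
      al <- align_runs(lapply(fit$runs, `[[`, "Q"))
      qdf <- data.frame(id = rownames(fit$runs[[1]]$Q),
                        round(al$mean_q, 4))
      names(qdf)[-1] <- paste0("Q", seq_len(k))
      put(qdf, sprintf("structure_Q_K%d.csv", k), digits = NULL)
      if (k == 2) res$q2 <- al$mean_q
    }
    ev <- evanno_delta_k(scan$lnpk)
    put(ev, "evanno_delta_k.csv", digits = NULL)
    opt <- attr(ev, "optimal_k")
    logline("optimal K by delta-K: ", opt)
    if (!is.na(opt) && as.character(opt) %in% names(scan$fits)) {
      al <- align_runs(lapply(scan$fits[[as.character(opt)]]$runs, `[[`, "Q"))
      grp <- assign_groups(al$mean_q, cfg$q_threshold)
      put(grp$assignments, "structure_membership.csv", digits = NULL)
      put(grp$counts, "structure_membership_counts.csv", digits = NULL)
      res$groups <- grp
    }
    res$structure <- scan
    res$evanno <- ev
  }

  if (cfg$do_pcoa) {
    pc <- stage("pcoa", pcoa(dm, n_axes = cfg$n_axes))
    cdf <- data.frame(id = rownames(pc$coordinates),
                      pop = if (!is.null(gm$pop)) gm$pop else NA,
                      pc$coordinates)
    put(cdf, "pcoa_coordinates.csv", digits = NULL)
    ev <- data.frame(axis = seq_along(pc$eigenvalues),
                     eigenvalue = pc$eigenvalues)
    put(ev, "pcoa_eigenvalues.csv", digits = NULL)
    res$pcoa <- pc
  }

  logline(sprintf("done in %.1fs; %d files",
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  length(files)))
  res$files <- c(files, log_path)
  invisible(res)
}
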