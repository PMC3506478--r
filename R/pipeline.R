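## End-to-end orchestration: one config drives conservation profiling,
## REL selection analysis and BGM co-evolution detection, joining all
## site-level results in reference-residue coordinates.

#' Build a run configuration
#'
#' Defaults follow the chitinase ortholog analysis settings: trim the
#' first 36 amino acids / 117 bp (unalignable signal-peptide region),
#' RCA with a 7-column window at a 0.5 SD threshold and K = 16 gamma
#' categories, REL Bayes-factor thresholds 50 (strong) / 10 (weak), BGM
#' with non-synonymous branch-count filter >= 3 and posterior >= 0.5.
#'
#' @param protein_alignment,codon_alignment,tree input file paths
#'   (FASTA, FASTA, Newick); `tree = "build"` requests BIONJ + ML branch
#'   lengths from the protein alignment.
#' @param reference_id reference sequence for residue numbering.
#' @param out_dir output directory.
#' @param stages character subset of `c("rca", "rel", "bgm")`.
#' @param trim_aa,trim_nt leading units to trim.
#' @param rca,rel,bgm stage parameter lists (partial overrides of the
#'   defaults are merged).
#' @param seed seed for all stochastic stages.
#' @return list of class `run_config`.
#' @export
run_config <- function(protein_alignment = NULL, codon_alignment = NULL,
                       tree = "build", reference_id = NULL,
                       out_dir = "sitesel_out",
                       stages = c("rca", "rel", "bgm"),
                       trim_aa = 36, trim_nt = 117,
                       rca = list(), rel = list(), bgm = list(),
                       seed = 1) {
  merge <- function(defaults, user) utils::modifyList(defaults, user)
  cfg <- list(
    protein_alignment = protein_alignment,
    codon_alignment = codon_alignment,
    tree = tree, reference_id = reference_id, out_dir = out_dir,
    stages = stages, trim_aa = trim_aa, trim_nt = trim_nt,
    rca = merge(list(window = 7, threshold = 0.5, K = 16), rca),
    rel = merge(list(constraints = "GTR", strong = 50, weak = 10,
                     n_starts = 3, maxit = 300), rel),
    bgm = merge(list(min_count = 3, pp = 0.5, max_parents = 2,
                     chain_length = 1e5, burn_in = 1e4), bgm),
    seed = seed)
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration as JSON
#' @param config a [run_config()].
#' @param path JSON file.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, cfg[intersect(names(cfg),
                                    names(formals(run_config)))])
}

.validate_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (st in config$stages) {
    if (st == "rca" && is.null(config$protein_alignment))
      stop("stage 'rca' requested but no protein alignment configured")
    if (st %in% c("rel", "bgm") && is.null(config$codon_alignment))
      stop("stage '", st, "' requested but no codon alignment configured")
  }
  for (p in c(config$protein_alignment, config$codon_alignment)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  if (!identical(config$tree, "build") && !file.exists(config$tree))
    stop("tree file not found: ", config$tree)
  invisible(TRUE)
}

#' Run the full site-level analysis pipeline
#'
#' Stages: (1) RCA conservation profile and variable-region calling on
#' the protein alignment; (2) REL 3x3 (dN, dS) fit, per-site Bayes
#' factors and site classification on the codon alignment; (3) BGM
#' co-evolution detection from the joint ancestral reconstruction under
#' the averaged REL model.  All raw stage outputs are written to
#' `config$out_dir` as TSV/JSON and joined into a per-residue site
#' report.  Outputs are a pure function of (inputs, config, seed).
#'
#' @param config a [run_config()].
#' @return list of class `run_result` with elements `profile`, `rel`,
#'   `rel_sites`, `bgm`, `coevolving`, `report`, `summary`.
#' @export
run_all <- function(config) {
  .validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[sitesel] ", sprintf(...))
  res <- list()

  ## inputs
  prot <- NULL; cod <- NULL
  if (!is.null(config$protein_alignment)) {
    prot <- read_alignment(config$protein_alignment, "protein")
    if (config$trim_aa > 0) prot <- trim_leading(prot, config$trim_aa)
  }
  if (!is.null(config$codon_alignment)) {
    cod_nt <- read_alignment(config$codon_alignment, "nucleotide")
    if (config$trim_nt > 0) cod_nt <- trim_leading(cod_nt, config$trim_nt)
    cod <- as_codon_alignment(cod_nt)
  }
  tree <- if (identical(config$tree, "build")) {
    src <- if (!is.null(prot)) prot else cod$base
    model <- if (!is.null(prot)) jtt_model() else gtr_model()
    log_msg("building BIONJ tree (%d sequences)", nrow(src))
    build_bionj_tree(src, model, optimize = TRUE)
  } else read_newick(config$tree)

  run_stage <- function(name, expr) {
    log_msg("stage %s ...", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           " (partial artifacts retained in ", config$out_dir, ")",
           call. = FALSE))
  }

  if ("rca" %in% config$stages) {
    res$profile <- run_stage("rca", rca_profile(
      prot, tree, K = config$rca$K, window = config$rca$window,
      threshold = config$rca$threshold,
      reference_id = config$reference_id))
    write_rca_tsv(res$profile, file.path(config$out_dir, "rca_profile.tsv"))
    jsonlite::write_json(res$profile$regions,
                         file.path(config$out_dir, "rca_regions.json"))
  }
  if ("rel" %in% config$stages || "bgm" %in% config$stages) {
    constraints <- if (is.character(config$rel$constraints))
      nucleotide_constraints(config$rel$constraints)
    else config$rel$constraints
    ref_pos <- if (!is.null(config$reference_id))
      build_reference_map(cod, config$reference_id)$column_to_residue
    res$rel <- run_stage("rel", fit_rel(
      cod, tree, constraints, n_starts = config$rel$n_starts,
      maxit = config$rel$maxit, ref_positions = ref_pos))
    res$rel_sites <- classify_sites(res$rel, config$rel$strong,
                                    config$rel$weak)
    write_rel_tsv(res$rel, file.path(config$out_dir, "rel_sites.tsv"),
                  strong_threshold = config$rel$strong,
                  weak_threshold = config$rel$weak)
    jsonlite::write_json(
      list(dn = res$rel$grid$dn_scaled, ds = res$rel$grid$ds_scaled,
           weights = res$rel$grid$weights, ratio = res$rel$grid$ratio,
           loglik = res$rel$loglik,
           constraints = as.list(constraints$mapping),
           positive_class = rel_positive_class(res$rel)),
      file.path(config$out_dir, "rel_fit.json"),
      auto_unbox = TRUE, digits = NA)
  }
  if ("bgm" %in% config$stages) {
    res$bgm <- run_stage("bgm", {
      model <- rel_mean_model(res$rel)
      anc <- joint_ancestral_codons(tree, cod, model)
      smap <- substitution_map(tree, cod, anc,
                               positions = res$rel$positions)
      fmap <- filter_sites(smap, config$bgm$min_count)
      if (nrow(fmap$matrix) < 2)
        stop("fewer than 2 sites pass the non-synonymous count filter")
      bgm_fit(fmap, max_parents = config$bgm$max_parents,
              chain_length = config$bgm$chain_length,
              burn_in = config$bgm$burn_in, seed = config$seed)
    })
    res$coevolving <- call_coevolving(res$bgm, config$bgm$pp)
    write_bgm_tsv(res$coevolving,
                  file.path(config$out_dir, "bgm_pairs.tsv"))
    jsonlite::write_json(
      list(edges = res$bgm$edge_posterior,
           groups = res$coevolving$groups,
           diagnostics = res$bgm$diagnostics),
      file.path(config$out_dir, "bgm_network.json"),
      auto_unbox = TRUE, digits = NA)
  }

  res$report <- cross_annotate(
    if (!is.null(res$profile)) res$profile else NULL,
    res$rel_sites, res$coevolving)
  if (!is.null(res$report))
    utils::write.table(res$report,
                       file.path(config$out_dir, "site_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  res$summary <- list(
    n_regions = if (!is.null(res$profile)) nrow(res$profile$regions),
    n_strong = if (!is.null(res$rel_sites))
      sum(res$rel_sites$category == "strong"),
    n_weak = if (!is.null(res$rel_sites))
      sum(res$rel_sites$category == "weak"),
    n_pairs = if (!is.null(res$coevolving)) nrow(res$coevolving$pairs),
    n_groups = if (!is.null(res$coevolving)) length(res$coevolving$groups))
  log_msg("done: %s", paste(names(res$summary), unlist(res$summary),
                            sep = "=", collapse = ", "))
  class(res) <- "run_result"
  res
}

#' Join stage outputs per reference residue
#'
#' Flags every analysed residue with the variable region containing it
#' (closed intervals), its REL classification and its co-evolution
#' group, and counts the overlap of positively selected sites with
#' called regions.
#'
#' @param profile a [rca_profile()] (or `NULL`).
#' @param rel_sites a [classify_sites()] data.frame (or `NULL`).
#' @param coevolving a [call_coevolving()] result (or `NULL`).
#' @return data.frame site report with attribute `overlap` (number of
#'   positively selected sites inside called regions), or `NULL` when
#'   no stage ran.
#' @export
cross_annotate <- function(profile = NULL, rel_sites = NULL,
                           coevolving = NULL) {
  positions <- integer(0)
  if (!is.null(profile))
    positions <- union(positions, profile$positions[!is.na(profile$positions)])
  if (!is.null(rel_sites)) positions <- union(positions, rel_sites$site)
  if (!length(positions)) return(NULL)
  positions <- sort(positions)
  df <- data.frame(residue = positions)
  if (!is.null(profile)) {
    idx <- match(df$residue, profile$positions)
    df$s <- profile$s_scores[idx]
    df$w <- profile$w_scores[idx]
    df$region <- NA_integer_
    for (i in seq_len(nrow(profile$regions))) {
      inside <- df$residue >= profile$regions$start[i] &
                df$residue <= profile$regions$end[i]
      df$region[inside] <- i
    }
    df$in_region <- !is.na(df$region)
  }
  if (!is.null(rel_sites)) {
    idx <- match(df$residue, rel_sites$site)
    df$rel_posterior <- rel_sites$posterior[idx]
    df$rel_bayes_factor <- rel_sites$bayes_factor[idx]
    df$rel_category <- rel_sites$category[idx]
  }
  if (!is.null(coevolving) && length(coevolving$groups)) {
    df$coev_group <- NA_integer_
    df$coev_partners <- ""
    for (g in seq_along(coevolving$groups)) {
      mem <- coevolving$groups[[g]]
      df$coev_group[df$residue %in% mem] <- g
      for (m in mem) {
        df$coev_partners[df$residue == m] <-
          paste(setdiff(mem, m), collapse = ",")
      }
    }
  }
  if (!is.null(profile) && !is.null(rel_sites)) {
    sel <- rel_sites$site[rel_sites$category %in% c("strong", "weak")]
    attr(df, "overlap") <-
      sum(df$in_region[match(sel, df$residue)], na.rm = TRUE)
  }
  df
}
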