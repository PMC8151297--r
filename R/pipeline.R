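#' Configure a full panel analysis
#'
#' @param genotype_file genotype matrix TSV (see [read_genotype_table()]).
#' @param marker_file optional marker definition TSV.
#' @param population_file optional two-column (accession, population) TSV;
#'   when absent the AMOVA stage requires labels embedded via `populations`.
#' @param out_dir output directory (created if needed).
#' @param stages character vector of enabled stages, any of
#'   `"stats"`, `"distance"`, `"tree"`, `"pcoa"`, `"amova"`, `"structure"`,
#'   `"select_markers"`.
#' @param seed global seed; stage seeds are derived as `seed + offset` with
#'   fixed per-stage offsets, so disabling one stage never shifts another.
#' @param amova_permutations,k_range,structure_reps,burn_in,n_iter,
#'   admix_threshold,accumulation_reps stage parameters.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotype_file, marker_file = NULL,
                            population_file = NULL, out_dir,
                            stages = c("stats", "distance", "tree", "pcoa",
                                       "amova", "structure",
                                       "select_markers"),
                            seed = 1L, amova_permutations = 1000L,
                            k_range = 1:10, structure_reps = 10L,
                            burn_in = 10000L, n_iter = 100000L,
                            admix_threshold = 0.7,
                            accumulation_reps = 100L) {
  known <- c("stats", "distance", "tree", "pcoa", "amova", "structure",
             "select_markers")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(genotype_file = genotype_file, marker_file = marker_file,
                 population_file = population_file, out_dir = out_dir,
                 stages = stages, seed = as.integer(seed),
                 amova_permutations = as.integer(amova_permutations),
                 k_range = as.integer(k_range),
                 structure_reps = as.integer(structure_reps),
                 burn_in = as.integer(burn_in), n_iter = as.integer(n_iter),
                 admix_threshold = admix_threshold,
                 accumulation_reps = as.integer(accumulation_reps)),
            class = "pipeline_config")
}

STAGE_SEED_OFFSETS <- c(stats = 101L, distance = 102L, tree = 103L,
                        pcoa = 104L, amova = 105L, structure = 106L,
                        select_markers = 107L)

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — per-locus diversity statistics,
#' Nei distance matrix, UPGMA tree, PCoA, codominant AMOVA, admixture-model
#' structure sweep with Evanno delta-K, and accumulation-curve plus greedy
#' minimum-marker-set selection — writing one TSV/Newick artifact per stage
#' and a JSON summary. Stage failures abort with a stage-named error;
#' artifacts of completed stages are retained.
#'
#' @param cfg a [pipeline_config()].
#' @return (invisibly) the summary list, also written to
#'   `<out_dir>/summary.json`.
#' @export
run_full_analysis <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  gm <- read_genotype_table(cfg$genotype_file,
                            populations = cfg$population_file)
  defs <- if (!is.null(cfg$marker_file)) read_marker_table(cfg$marker_file)
  summary <- list(n_accessions = length(gm$accession_ids),
                  n_markers = length(gm$marker_ids), seed = cfg$seed,
                  stages = cfg$stages)
  out <- function(f) file.path(cfg$out_dir, f)
  run_stage <- function(name, fn) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    set.seed(cfg$seed + STAGE_SEED_OFFSETS[[name]])
    tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  stats <- NULL
  run_stage("stats", function() {
    stats <<- locus_stats_table(gm)
    write.table(stats, out("locus_stats.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    ps <- summarize_panel(stats, defs)
    summary$diversity <<- list(n_polymorphic = ps$n_polymorphic,
                               n_monomorphic = ps$n_monomorphic,
                               mean_gd = unname(ps$mean_all["gd"]),
                               mean_he = unname(ps$mean_all["he"]),
                               mean_maf_polymorphic =
                                 unname(ps$mean_polymorphic["maf"]))
  })
  dm <- NULL
  run_stage("distance", function() {
    dm <<- distance_matrix(gm)
    write_distance_tsv(dm, out("nei_distance.tsv"))
    summary$mean_distance <<- mean(dm$d[upper.tri(dm$d)])
  })
  run_stage("tree", function() {
    if (is.null(dm)) dm <<- distance_matrix(gm)
    tree <- upgma(dm)
    writeLines(to_newick(tree), out("upgma.nwk"))
    summary$tree_height <<- tree$height
  })
  run_stage("pcoa", function() {
    if (is.null(dm)) dm <<- distance_matrix(gm)
    res <- pcoa(dm)
    write_pcoa_tsv(res, out("pcoa_coordinates.tsv"))
    summary$pcoa_percent_variance <<-
      res$percent_variance[seq_len(min(3, length(res$percent_variance)))]
  })
  run_stage("amova", function() {
    am <- amova_codominant(gm, n_perm = cfg$amova_permutations,
                           seed = cfg$seed + STAGE_SEED_OFFSETS[["amova"]])
    write_amova_tsv(am, out("amova.tsv"))
    summary$amova <<- list(f_st = am$f_st, p_value = am$p_value)
  })
  run_stage("structure", function() {
    sw <- structure_sweep(gm, cfg$k_range, n_reps = cfg$structure_reps,
                          burn_in = cfg$burn_in, n_iter = cfg$n_iter,
                          seed = cfg$seed + STAGE_SEED_OFFSETS[["structure"]])
    ev <- evanno_delta_k(sw)
    write.table(ev, out("evanno.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    k_opt <- attr(ev, "optimal_k")
    best <- sw$runs[[paste0("K", k_opt)]][[1]]
    qdf <- data.frame(accession = rownames(best$q), best$q,
                      membership = classify_membership(best,
                                                       cfg$admix_threshold),
                      check.names = FALSE)
    write.table(qdf, out("structure_q.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    summary$structure <<- list(optimal_k = k_opt,
                               delta_k = max(ev$delta_k, na.rm = TRUE))
  })
  run_stage("select_markers", function() {
    ac <- accumulation_curve(gm, r = cfg$accumulation_reps,
                             seed = cfg$seed +
                               STAGE_SEED_OFFSETS[["select_markers"]])
    write.table(data.frame(n_loci = ac$sizes, mean_mlg = ac$mean,
                           q25 = ac$q25, q75 = ac$q75),
                out("accumulation_curve.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    sel <- greedy_minimal_marker_set(gm, stats = stats)
    writeLines(sel$selected, out("selected_markers.txt"))
    if (sel$n_selected >= 1L && length(gm$accession_ids) >= 2L) {
      sub <- subset_genotypes(gm, markers = sel$selected)
      writeLines(to_newick(upgma(distance_matrix(sub))),
                 out("selected_markers.nwk"))
    }
    summary$selection <<- list(n_selected = sel$n_selected,
                               complete = sel$complete,
                               markers = sel$selected)
  })
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(summary)
}
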