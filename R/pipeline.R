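#' Pipeline configuration
#'
#' Paths to the inputs plus the tunable parameters of every stage, echoed
#' into `summary.json` for provenance. All referenced files must exist.
#'
#' @param genome,gff3,pspg_block,anchors,dictionary,expression,treatment,ct
#'   Input file paths (FASTA genome, GFF3 annotation, aligned 44-aa PSPG
#'   reference block FASTA, anchor TSV `id`/`group`, cis-element dictionary
#'   TSV, wide expression TSV, control/treated TSV, long Ct TSV).
#' @param p_threshold,n_shuffles Motif-scan significance threshold and
#'   shuffle-null size.
#' @param length_window Protein length window retained by the family filter.
#' @param gap_open,gap_extend Alignment gap penalties.
#' @param bootstrap_replicates Bootstrap replicates for branch supports.
#' @param tolerance_columns Intron-class column linkage tolerance.
#' @param promoter_length Promoter length in bp.
#' @param tau Expression threshold.
#' @param pseudocount,fc_threshold Fold-change parameters.
#' @param ct_reference,ct_calibrator Housekeeping gene and calibrator
#'   condition for the Ct table.
#' @param seed Integer seed driving the shuffle null and bootstrap.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, gff3, pspg_block, anchors, dictionary,
                            expression = NULL, treatment = NULL, ct = NULL,
                            p_threshold = 1e-5, n_shuffles = 1000L,
                            length_window = c(300, 600),
                            gap_open = 10, gap_extend = 0.5,
                            bootstrap_replicates = 1000L,
                            tolerance_columns = 3,
                            promoter_length = 1500L,
                            tau = 0, pseudocount = 1, fc_threshold = 1,
                            ct_reference = "EF1a", ct_calibrator = "0h",
                            seed = 1L) {
  cfg <- as.list(environment())
  files <- purrr::compact(cfg[c("genome", "gff3", "pspg_block", "anchors",
                                "dictionary", "expression", "treatment",
                                "ct")])
  missing <- files[!vapply(unlist(files), file.exists, logical(1))]
  if (length(missing) > 0) {
    stop("pipeline_config(): missing input file(s): ",
         paste(names(missing), "=", unlist(missing), collapse = ", "))
  }
  structure(cfg, class = "pipeline_config")
}

#' Convenience: pipeline configuration from a simulation
#'
#' @param sim Result of [simulate_ugt_study()].
#' @param ... Overrides passed to [pipeline_config()].
#' @return A `pipeline_config` pointing at the simulated files.
#' @export
pipeline_config_from_sim <- function(sim, ...) {
  p <- sim$paths
  args <- list(genome = p$genome, gff3 = p$gff3, pspg_block = p$pspg_block,
               anchors = p$anchors, dictionary = p$dictionary,
               expression = p$expression, treatment = p$treatment, ct = p$ct)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(pipeline_config, args)
}

#' Chromosome location table of the family
#'
#' @param family Family tibble carrying `gene_id`.
#' @param gene_models Gene-model tibble from [read_gff3()].
#' @param groups Optional group tibble (`gene_id`, `group`).
#' @return A list: `table` (per-gene locations sorted by chromosome then
#'   start) and `counts` (per-chromosome gene counts).
#' @export
chromosome_table <- function(family, gene_models, groups = NULL) {
  tab <- gene_models %>%
    dplyr::filter(.data$gene_id %in% family$gene_id) %>%
    dplyr::mutate(start = purrr::map_int(.data$cds, ~ min(.x$start)),
                  end = purrr::map_int(.data$cds, ~ max(.x$end))) %>%
    dplyr::select("chrom", "start", "end", "strand", "gene_id")
  if (!is.null(groups)) {
    tab <- dplyr::left_join(tab, groups[c("gene_id", "group")], by = "gene_id")
  }
  tab <- dplyr::arrange(tab, .data$chrom, .data$start)
  list(table = tab, counts = dplyr::count(tab, .data$chrom, name = "n_genes"))
}

#' Run the full family-analysis pipeline
#'
#' Executes the stages in dependency order -- family identification,
#' alignment, NJ tree with bootstrap, group assignment, intron classes,
#' promoter elements, expression calls, fold changes, 2^-ddCt -- writing
#' plain TSV/Newick/JSON outputs plus a `summary.json` and `run.log` to
#' `out_dir`. Deterministic for a fixed config (byte-identical
#' `summary.json` across reruns). Count identities (groups sum to family
#' size, phases sum to intron count, chromosomes sum to family size) are
#' asserted on every run.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with `summary` and all stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  stage <- function(name, expr) {
    note("[stage] ", name)
    tryCatch(expr, error = function(e) {
      note("[error] stage ", name, ": ", conditionMessage(e))
      writeLines(log_lines, file.path(out_dir, "run.log"))
      stop("run_pipeline(): stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE)
    })
  }
  out <- function(name) file.path(out_dir, name)

  genome <- stage("read_genome", read_fasta(config$genome))
  genes <- stage("read_annotation", read_gff3(config$gff3, genome = genome))
  genes <- stage("spliced_cds",
                 withCallingHandlers(
                   add_proteins(spliced_cds(genome, genes)),
                   message = function(m) {
                     note(sub("\n$", "", conditionMessage(m)))
                     invokeRestart("muffleMessage")
                   }))
  translatable <- genes[!genes$pseudo_cds & !genes$internal_stop, ]
  for (id in setdiff(genes$gene_id, translatable$gene_id)) {
    note("[drop] ", id, " reason=",
         ifelse(genes$pseudo_cds[genes$gene_id == id], "pseudo_cds",
                "internal_stop"))
  }

  model <- stage("pspg_model",
                 build_pspg_model(read_fasta(config$pspg_block,
                                             moltype = "protein")$seq))
  proteins <- tibble::tibble(gene_id = translatable$gene_id,
                             protein = translatable$protein)
  hits <- stage("motif_scan",
                scan_proteins(proteins, model,
                              n_shuffles = config$n_shuffles,
                              seed = config$seed))
  classified <- stage("classify",
                      suppressMessages(classify_candidates(
                        proteins, hits, p_threshold = config$p_threshold,
                        length_window = config$length_window)))
  for (i in which(!classified$retained)) {
    note("[drop] ", classified$gene_id[i], " reason=", classified$reason[i])
  }
  family <- family_members(classified)
  note("[family] ", nrow(family), " member(s) retained of ",
       nrow(classified), " scanned")

  stats_tbl <- stage("protein_stats",
                     suppressWarnings(protein_stats(
                       family[c("gene_id", "protein")])))
  fam_models <- dplyr::semi_join(genes, family, by = "gene_id")
  family_tbl <- family %>%
    dplyr::rename(motif_start = "start") %>%
    dplyr::left_join(dplyr::select(stats_tbl, -"length"), by = "gene_id") %>%
    dplyr::left_join(
      fam_models %>%
        dplyr::mutate(start = purrr::map_int(.data$cds, ~ min(.x$start)),
                      end = purrr::map_int(.data$cds, ~ max(.x$end))) %>%
        dplyr::select("gene_id", "transcript_id", "chrom", "start", "end",
                      "strand", "exon_count", "n_transcripts"),
      by = "gene_id") %>%
    dplyr::select("gene_id", "transcript_id", "length", "mw_kda", "pi",
                  "chrom", "start", "end", "strand", "exon_count",
                  "n_transcripts", "motif_start", "score", "empirical_p")
  readr::write_tsv(family_tbl, out("family.tsv"))

  aln <- stage("alignment",
               progressive_align(family[c("gene_id", "protein")],
                                 gap_open = config$gap_open,
                                 gap_extend = config$gap_extend))
  write_fasta(tibble::tibble(id = aln$gene_id, seq = aln$aligned),
              out("alignment.fasta"))

  phylogeny <- stage("phylogeny",
                     bootstrap_support(aln,
                                       replicates = config$bootstrap_replicates,
                                       seed = config$seed + 1L))
  write_phylogeny(phylogeny, out("tree.nwk"))

  anchors <- stage("anchors",
                   readr::read_tsv(config$anchors,
                                   col_types = readr::cols(.default = "c")))
  groups <- stage("groups", assign_groups(phylogeny, anchors))
  readr::write_tsv(groups, out("groups.tsv"))

  records <- stage("introns", {
    rec <- suppressMessages(gene_introns(fam_models))
    if (nrow(rec) > 0) {
      rec <- cluster_intron_classes(project_introns(rec, aln),
                                    tolerance = config$tolerance_columns)
    } else {
      rec$column <- integer(0)
      rec$class_label <- character(0)
    }
    rec
  })
  readr::write_tsv(records, out("introns.tsv"))
  class_summary <- conservation_table(records)
  readr::write_tsv(class_summary, out("intron_classes.tsv"))
  readr::write_tsv(gain_loss_matrix(records, groups), out("gainloss.tsv"))

  promoters <- stage("promoters",
                     extract_upstream(genome, fam_models,
                                      length = config$promoter_length))
  dict <- stage("dictionary", load_element_dictionary(config$dictionary))
  cis_hits <- stage("promoter_scan", scan_promoters(promoters, dict))
  readr::write_tsv(cis_hits, out("promoter_hits.tsv"))
  cis_counts <- categorize_counts(cis_hits, gene_ids = promoters$gene_id)
  readr::write_tsv(cis_counts$counts, out("promoter_counts.tsv"))
  readr::write_tsv(cis_counts$bins, out("promoter_bins.tsv"))

  calls <- NULL; tallies <- NULL; fc <- NULL; rel <- NULL
  if (!is.null(config$expression)) {
    mat <- stage("expression",
                 readr::read_tsv(config$expression, show_col_types = FALSE))
    calls <- call_expressed(mat, tau = config$tau)
    tallies <- tissue_specific_tally(calls,
                                     tissues = setdiff(names(mat), "gene_id"))
    readr::write_tsv(
      calls %>% dplyr::mutate(
        expressed_in = purrr::map_chr(.data$expressed_in, paste,
                                      collapse = ",")),
      out("expression_calls.tsv"))
  }
  if (!is.null(config$treatment)) {
    fc <- stage("fold_changes",
                fold_changes(readr::read_tsv(config$treatment,
                                             show_col_types = FALSE),
                             pseudocount = config$pseudocount,
                             threshold = config$fc_threshold))
    readr::write_tsv(fc, out("fold_changes.tsv"))
  }
  if (!is.null(config$ct)) {
    rel <- stage("ddct",
                 ddct(readr::read_tsv(config$ct, show_col_types = FALSE),
                      reference_gene = config$ct_reference,
                      calibrator = config$ct_calibrator))
    readr::write_tsv(rel, out("ddct.tsv"))
  }

  chrom_tab <- chromosome_table(family, fam_models, groups)
  readr::write_tsv(chrom_tab$table, out("chromosomes.tsv"))

  introns_per_gene <- records %>%
    dplyr::count(.data$gene_id) %>%
    dplyr::right_join(tibble::tibble(gene_id = family$gene_id),
                      by = "gene_id") %>%
    tidyr::replace_na(list(n = 0L))
  phase_tally <- vapply(0:2, function(p) sum(records$phase == p), integer(1))

  summary <- list(
    n_genes_scanned = nrow(classified),
    family_size = nrow(family),
    dropped = as.list(table(classified$reason[!classified$retained])),
    groups = as.list(table(groups$group)),
    chromosomes = stats::setNames(as.list(chrom_tab$counts$n_genes),
                                  chrom_tab$counts$chrom),
    introns = list(
      n_total = nrow(records),
      n_intron_bearing_genes = sum(introns_per_gene$n > 0),
      n_intronless_genes = sum(introns_per_gene$n == 0),
      by_intron_count = as.list(table(introns_per_gene$n)),
      by_phase = list(phase0 = phase_tally[1], phase1 = phase_tally[2],
                      phase2 = phase_tally[3]),
      n_classes = nrow(class_summary)
    ),
    promoter = list(
      n_genes = nrow(cis_counts$counts),
      genes_without_light = sum(cis_counts$counts$light == 0),
      genes_without_hormone = sum(cis_counts$counts$hormone == 0),
      genes_without_stress = sum(cis_counts$counts$stress == 0)
    ),
    expression = if (!is.null(calls)) list(
      n_expressed = sum(!calls$dropped),
      n_dropped_zero = sum(calls$dropped),
      tissue_specific = stats::setNames(as.list(tallies$n_specific),
                                        tallies$tissue)
    ),
    treatment = if (!is.null(fc)) list(
      n_upregulated = sum(fc$upregulated),
      n_downregulated = sum(fc$downregulated)
    ),
    parameters = config[c("p_threshold", "n_shuffles", "length_window",
                          "gap_open", "gap_extend", "bootstrap_replicates",
                          "tolerance_columns", "promoter_length", "tau",
                          "pseudocount", "fc_threshold", "seed")]
  )

  # count identities, asserted on every run
  stopifnot(sum(unlist(summary$groups)) == summary$family_size,
            sum(unlist(summary$introns$by_phase)) == summary$introns$n_total,
            sum(unlist(summary$chromosomes)) == summary$family_size)

  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  note("[done] pipeline complete")
  writeLines(log_lines, out("run.log"))

  invisible(list(summary = summary, family = family_tbl,
                 classified = classified, alignment = aln,
                 phylogeny = phylogeny, groups = groups, introns = records,
                 intron_classes = class_summary, promoter_hits = cis_hits,
                 promoter_counts = cis_counts, expression_calls = calls,
                 tissue_tally = tallies, fold_changes = fc, ddct = rel,
                 chromosome_table = chrom_tab, out_dir = out_dir))
}
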