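# Readers and writers for the plain-text formats the pipeline consumes
# and produces. All genomic output is 0-based half-open (BED-style);
# conversion to 1-based coordinates is confined to VCF I/O.

#' Read a per-CpG methylation table
#'
#' Accepts bedGraph-like TSV (chrom, start, end, methylation, coverage)
#' or per-CpG TSV (chrom, pos, methylation, coverage); auto-detected from
#' the column count. Lines starting with `#` or `track` are skipped.
#'
#' @param path file path.
#' @param line_id,state labels stored on the track.
#' @return a `methylome_track`.
#' @export
read_methylation_table <- function(path, line_id = "line1",
                                   state = "parental") {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty methylation table: ", path)
    return(new_methylome_track(line_id, state,
      data.frame(chrom = character(), pos = numeric(),
                 methylation = numeric(), coverage = numeric())))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- unique(lengths(parts))
  if (length(ncol) != 1 || !(ncol %in% c(4, 5)))
    stop("malformed methylation table (expect 4 or 5 tab-separated columns)")
  m <- do.call(rbind, parts)
  pos <- as.numeric(m[, 2])
  meth_col <- if (ncol == 5) 4 else 3
  meth <- as.numeric(m[, meth_col])
  cov <- as.numeric(m[, ncol])
  bad <- which(is.na(pos) | is.na(meth) | is.na(cov) | meth < 0 | meth > 1)
  if (length(bad) > 0)
    stop(sprintf("parse error in %s at line %d: %s", path, bad[1],
                 lines[bad[1]]))
  new_methylome_track(line_id, state,
    data.frame(chrom = m[, 1], pos = pos, methylation = meth,
               coverage = cov, stringsAsFactors = FALSE))
}

#' Write a methylome track as bedGraph-like TSV
#'
#' Columns: chrom, start, end (= start + 1), methylation, coverage.
#'
#' @param track a `methylome_track`.
#' @param path output path.
#' @export
write_methylation_table <- function(track, path) {
  rec <- track$records
  utils::write.table(
    data.frame(rec$chrom, rec$pos, rec$pos + 1, rec$methylation,
               rec$coverage),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' Read a BED file into a merged interval set
#'
#' BED3+; columns past the third are ignored. `track`/`browser`/`#`
#' header lines are skipped; output is sorted and merged, 0-based
#' half-open preserved.
#'
#' @param path file path.
#' @param merge merge overlapping/bookended intervals (default TRUE).
#' @return interval data.frame.
#' @export
read_intervals <- function(path, merge = TRUE) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) return(intervals())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3)) stop("BED line with fewer than 3 columns")
  m <- do.call(rbind, lapply(parts, function(p) p[1:3]))
  s <- as.numeric(m[, 2]); e <- as.numeric(m[, 3])
  bad <- which(is.na(s) | is.na(e) | e <= s)
  if (length(bad) > 0)
    stop(sprintf("invalid BED interval at line %d: %s", bad[1], lines[bad[1]]))
  iv <- intervals(m[, 1], s, e)
  if (merge) merge_intervals(iv) else iv[order(iv$chrom, iv$start), ]
}

#' Write intervals (or DMRs) as BED
#'
#' BED6 when `name`/`score`/`strand` information is available, BED3
#' otherwise.
#'
#' @param df interval data.frame; optional columns `name` and `score`.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  out <- data.frame(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
                    format(df$end, scientific = FALSE, trim = TRUE))
  if (!is.null(df$name) || !is.null(df$score)) {
    out$name <- if (is.null(df$name)) "." else df$name
    out$score <- if (is.null(df$score)) 0 else df$score
    out$strand <- "."
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Write a variant table as minimal VCF
#'
#' CHROM/POS/REF/ALT plus per-sample `AF:DP` FORMAT fields, one sample
#' column per `vaf_*`/`cov_*` pair. POS is 1-based per the VCF spec.
#'
#' @param variants data.frame from [generate_variants()] or compatible.
#' @param path output path.
#' @export
write_vcf <- function(variants, path) {
  samples <- sub("^vaf_", "", grep("^vaf_", names(variants), value = TRUE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  if (nrow(variants) > 0) {
    fields <- sapply(samples, function(s)
      paste0(signif(variants[[paste0("vaf_", s)]], 6), ":",
             variants[[paste0("cov_", s)]]))
    if (nrow(variants) == 1) fields <- matrix(fields, 1)
    body <- cbind(variants$chrom, variants$pos + 1, ".", variants$ref,
                  variants$alt, ".", "PASS", ".", "AF:DP", fields)
    writeLines(apply(body, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a minimal VCF written by [write_vcf()]
#'
#' @param path file path.
#' @return data.frame with chrom, pos (0-based), ref, alt and per-sample
#'   `vaf_*`/`cov_*` columns.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  header <- grep("^#CHROM", lines, value = TRUE)
  if (length(header) != 1) stop("missing #CHROM header line")
  cols <- strsplit(header, "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- lines[!grepl("^#", lines)]
  empty_df <- function() {
    d <- data.frame(chrom = character(), pos = numeric(), ref = character(),
                    alt = character(), stringsAsFactors = FALSE)
    for (s in samples) { d[[paste0("vaf_", s)]] <- numeric(0)
                         d[[paste0("cov_", s)]] <- numeric(0) }
    d
  }
  if (length(body) == 0) return(empty_df())
  m <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  d <- data.frame(chrom = m[, 1], pos = as.numeric(m[, 2]) - 1,
                  ref = m[, 4], alt = m[, 5], stringsAsFactors = FALSE)
  fmt <- strsplit(m[1, 9], ":")[[1]]
  i_af <- match("AF", fmt); i_dp <- match("DP", fmt)
  if (is.na(i_af)) stop("VCF FORMAT lacks AF")
  for (j in seq_along(samples)) {
    parts <- strsplit(m[, 9 + j], ":", fixed = TRUE)
    d[[paste0("vaf_", samples[j])]] <-
      as.numeric(vapply(parts, `[`, "", i_af))
    d[[paste0("cov_", samples[j])]] <- if (!is.na(i_dp))
      as.numeric(vapply(parts, `[`, "", i_dp)) else NA_real_
  }
  d
}

#' Read a gene-level log2 fold-change table
#'
#' TSV with header: gene_id, log2fc_P_vs_R, log2fc_P12_vs_R.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_log2fc_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc_P_vs_R", "log2fc_P12_vs_R")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop("log2FC table missing columns: ", paste(miss, collapse = ", "))
  d
}

#' Assemble and validate a pipeline configuration
#'
#' @param seed global seed (propagated to every stage).
#' @param output_dir directory for stage outputs and the run manifest.
#' @param sim a [sim_config()] for the simulate stage.
#' @param dmr a [dmr_call_params()].
#' @param reversion a [reversion_params()].
#' @param enrichment an [enrichment_params()].
#' @param clonality a [clonality_params()].
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "call_dmrs", "score_reversion", "annotate", "enrich",
#'   "clonality")` in that order.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, output_dir = tempfile("dmrevert_run"),
                            sim = sim_config(seed = seed),
                            dmr = dmr_call_params(),
                            reversion = reversion_params(),
                            enrichment = enrichment_params(seed = seed),
                            clonality = clonality_params(),
                            stages = c("simulate", "call_dmrs",
                                       "score_reversion", "annotate",
                                       "enrich", "clonality")) {
  all_stages <- c("simulate", "call_dmrs", "score_reversion", "annotate",
                  "enrich", "clonality")
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(seed = as.integer(seed), output_dir = output_dir,
                 sim = sim, dmr = dmr, reversion = reversion,
                 enrichment = enrichment, clonality = clonality,
                 stages = stages),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  obj <- lapply(unclass(config), function(x)
    if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  pipeline_config(
    seed = obj$seed, output_dir = obj$output_dir,
    sim = do.call(sim_config, obj$sim),
    dmr = do.call(dmr_call_params, obj$dmr),
    reversion = do.call(reversion_params, obj$reversion),
    enrichment = do.call(enrichment_params, obj$enrichment),
    clonality = do.call(clonality_params, obj$clonality),
    stages = obj$stages)
}

#' Run the full synthetic-data analysis pipeline
#'
#' simulate -> call_dmrs -> score_reversion -> annotate -> enrich ->
#' clonality, each stage skippable via `config$stages`. Stage outputs are
#' written as TSV/BED/VCF/JSON under `config$output_dir` together with a
#' machine-readable manifest (parameters, seed, package version, file
#' checksums). A stage failure halts the run with the stage name;
#' outputs of completed stages remain on disk.
#'
#' @param config a [pipeline_config()].
#' @return named list of in-memory stage results (invisible file paths
#'   in `$manifest$files`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  files <- character(0)
  emit <- function(name, writer) {
    path <- file.path(config$output_dir, name)
    writer(path)
    files[[name]] <<- path
    path
  }
  run_stage <- function(name, fun) {
    if (!(name %in% config$stages)) return(NULL)
    tryCatch(fun(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  run_stage("simulate", function() {
    genome <- generate_genome(config$sim)
    meth <- generate_methylomes(genome, config$sim)
    genome <- generate_features(genome, meth$truth, config$sim)
    vars <- generate_variants(genome, config$sim)
    expr <- generate_expression(config$sim)
    res$genome <<- genome; res$methylomes <<- meth
    res$variants <<- vars; res$expression <<- expr
    for (nm in names(meth$tracks))
      emit(paste0("methylation_", nm, ".bedgraph"), function(p)
        write_methylation_table(meth$tracks[[nm]], p))
    emit("islands.bed", function(p) write_bed(genome$islands, p))
    for (tn in names(genome$feature_tracks))
      emit(paste0("features_", tn, ".bed"), function(p)
        write_bed(genome$feature_tracks[[tn]], p))
    emit("variants.vcf", function(p) write_vcf(vars$variants, p))
    emit("log2fc.tsv", function(p)
      utils::write.table(expr, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
    emit("truth_dmrs.json", function(p)
      jsonlite::write_json(meth$truth, p, digits = NA))
  })

  run_stage("call_dmrs", function() {
    dmrs <- call_dmrs(res$methylomes$tracks, config$dmr)
    res$dmrs <<- dmrs
    emit("dmrs.tsv", function(p)
      utils::write.table(dmrs, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  })

  run_stage("score_reversion", function() {
    cls <- classify_reverting_dmrs(res$dmrs, config$reversion)
    res$reversion <<- cls
    emit("dmrs_scored.tsv", function(p)
      utils::write.table(cls$dmrs, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  })

  run_stage("annotate", function() {
    genome <- res$genome
    ctx <- build_cpg_context(genome$islands, genome$chromosomes)
    gctx <- build_gene_context(genome$genes, genome$exons,
                               genome$chromosomes)
    regions <- res$dmrs[, c("chrom", "start", "end")]
    whole <- intervals(names(genome$chromosomes), 0,
                       unname(genome$chromosomes))
    comp <- annotate_region_context(regions, ctx)
    bg <- annotate_region_context(whole, ctx)
    gcomp <- annotate_region_context(regions, gctx)
    gbg <- annotate_region_context(whole, gctx)
    res$context <<- list(
      cpg = comp, cpg_background = bg,
      cpg_chisq = composition_chisq(comp, bg),
      gene = gcomp, gene_background = gbg,
      gene_chisq = composition_chisq(gcomp, gbg))
    emit("context_composition.tsv", function(p)
      utils::write.table(rbind(cbind(partition = "cpg", comp),
                               cbind(partition = "gene", gcomp)),
                         p, sep = "\t", quote = FALSE, row.names = FALSE))
  })

  run_stage("enrich", function() {
    regions <- res$dmrs[, c("chrom", "start", "end")]
    panel <- enrichment_panel(regions, res$genome$feature_tracks,
                              res$genome, config$enrichment)
    res$enrichment <<- panel
    emit("enrichment.tsv", function(p)
      utils::write.table(panel, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  })

  run_stage("clonality", function() {
    v <- res$variants$variants
    v$vclass <- classify_variants(v$vaf_parental, v$vaf_resistant,
                                  config$clonality)
    vpr <- v[v$vclass == "VpR", , drop = FALSE]
    dens <- if (nrow(vpr) >= 2)
      vaf_density(vpr$vaf_resistant, config$clonality$kde_bandwidth)
    else NULL
    filt <- wgbs_validation_filter(v, config$clonality)
    pers <- persistence_check(filt[filt$vclass == "VpR", , drop = FALSE],
                              filt[filt$vclass == "VpP", , drop = FALSE])
    res$clonality <<- list(variants = v, vaf_density = dens,
                           persistence = pers,
                           per_chromosome = per_chromosome_vaf(
                             vpr, params = config$clonality))
    emit("variants_classified.tsv", function(p)
      utils::write.table(v, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  })

  manifest <- list(
    package = "dmrevert",
    version = as.character(utils::packageVersion("dmrevert")),
    seed = config$seed,
    stages = config$stages,
    parameters = list(sim = unclass(config$sim),
                      dmr = unclass(config$dmr),
                      reversion = unclass(config$reversion),
                      enrichment = unclass(config$enrichment),
                      clonality = unclass(config$clonality)),
    files = lapply(files, function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
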