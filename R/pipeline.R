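#' Assemble per-chromosome column sets from alignment blocks
#'
#' Concatenates blocks in reference order into one [site_columns()] per
#' reference sequence (species missing from a block contribute N), with
#' the reference coordinate of every column attached — the input both
#' rho estimation and element calling consume.
#'
#' @param blocks list of `AlignmentBlock`s.
#' @return named list per reference sequence:
#'   `list(columns = site_columns, refpos = integer)`.
#' @export
alignment_columns <- function(blocks) {
  idx <- ref_block_index(blocks)
  species <- unique(unlist(lapply(blocks, function(b) b$species)))
  out <- list()
  for (sq in names(idx$tab)) {
    tab <- idx$tab[[sq]]
    mats <- list(); refpos <- list()
    for (j in seq_len(nrow(tab))) {
      b <- blocks[[tab$block[j]]]
      cm <- block_char_matrix(b)
      full <- matrix("N", nrow = length(species), ncol = ncol(cm),
                     dimnames = list(species, NULL))
      full[b$species, ] <- cm
      mats[[j]] <- full
      refpos[[j]] <- block_pos_map(b)[1, ]
    }
    out[[sq]] <- list(columns = site_columns(do.call(cbind, mats)),
                      refpos = unlist(refpos))
  }
  out
}

stage_seed <- function(seed, stage) (seed * 97L + stage * 1009L) %% 2147483647L

#' Run the whole loss-detection pipeline on a simulated data set
#'
#' Orchestrates simulate -> fit-neutral -> estimate-rho -> call-elements
#' -> define-cnes -> classify -> call-losses -> enrich, writing every
#' stage output under `out_dir` and a JSON manifest with per-file MD5
#' checksums, timings and the config snapshot. Stage RNG seeds are
#' derived deterministically from the config seed, so two runs of the
#' same config produce identical files; with `resume = TRUE`, stages
#' whose outputs already match the manifest checksums are skipped.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param params [hmm_params()] for element calling.
#' @param terms optional data.frame (`gene_id`, `term_id`) for the
#'   enrichment stage; if NULL a two-term placeholder map over the
#'   planted genes is generated (real runs supply GO-style annotations).
#' @param resume skip stages with up-to-date outputs.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, params = hmm_params(),
                         terms = NULL, resume = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (resume && file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else list(stages = list())
  manifest$seed <- config$seed
  manifest$version <- as.character(utils::packageVersion("cneloss"))
  manifest$config <- list(
    n_elements = config$n_elements,
    background_length = config$background_length,
    rho_conserved = config$rho_conserved,
    loss_plan = as.list(config$loss_plan),
    gap_plan = as.list(config$gap_plan),
    gamma = params$gamma, omega = params$omega, seed = config$seed)

  uptodate <- function(stage, outputs) {
    if (!resume) return(FALSE)
    st <- manifest$stages[[stage]]
    if (is.null(st)) return(FALSE)
    all(vapply(outputs, file.exists, TRUE)) &&
      identical(unname(unlist(st$checksums)),
                unname(tools::md5sum(unlist(outputs))))
  }
  record <- function(stage, outputs, t0) {
    manifest$stages[[stage]] <<- list(
      outputs = as.list(unname(unlist(outputs))),
      checksums = as.list(unname(tools::md5sum(unlist(outputs)))),
      seconds = round(as.numeric(Sys.time()) - t0, 2))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  msg <- function(...) message("[cneloss] ", ...)

  # -- stage 1: simulate ----------------------------------------------------
  fx <- file.path(out_dir, "data")
  fx_files <- file.path(fx, c(paste0(config$tree$tip.label, ".fa"),
                              "alignment.maf", "genes.gff3",
                              "truth_elements.bed", "truth_status.tsv"))
  if (!uptodate("simulate", fx_files)) {
    t0 <- as.numeric(Sys.time()); msg("simulate")
    sim <- evolve_alignment(config)
    emit_fixtures(sim, fx)
    record("simulate", fx_files, t0)
  } else msg("simulate: up to date")

  blocks <- read_maf(file.path(fx, "alignment.maf"))
  ann <- read_gff3(file.path(fx, "genes.gff3"))
  genomes <- lapply(config$tree$tip.label, function(sp)
    read_fasta(file.path(fx, paste0(sp, ".fa")), species_id = sp,
               min_n_run = config$min_n_run))
  names(genomes) <- config$tree$tip.label

  # -- stage 2: fit neutral model -------------------------------------------
  model_path <- file.path(out_dir, "model.json")
  if (!uptodate("fit_neutral", model_path)) {
    t0 <- as.numeric(Sys.time()); msg("fit-neutral")
    cols4d <- extract_4d_columns(blocks, ann)
    fit <- fit_neutral_model(cols4d, config$tree)
    write_model_json(fit$model, fit$tree, model_path)
    record("fit_neutral", model_path, t0)
  } else msg("fit-neutral: up to date")
  mj <- read_model_json(model_path)

  # -- stage 3: estimate rho ------------------------------------------------
  rho_path <- file.path(out_dir, "rho.json")
  cols <- alignment_columns(blocks)
  if (!uptodate("estimate_rho", rho_path)) {
    t0 <- as.numeric(Sys.time()); msg("estimate-rho")
    est <- estimate_rho(lapply(cols, `[[`, "columns"), mj$model, mj$tree,
                        params)
    jsonlite::write_json(list(rho = est$rho,
                              rho_per_chrom = est$rho_per_chrom,
                              boundary = est$boundary),
                         rho_path, auto_unbox = TRUE, digits = NA)
    record("estimate_rho", rho_path, t0)
  } else msg("estimate-rho: up to date")
  rho <- jsonlite::read_json(rho_path)$rho

  # -- stage 4: call elements -----------------------------------------------
  el_path <- file.path(out_dir, "elements.bed")
  if (!uptodate("call_elements", el_path)) {
    t0 <- as.numeric(Sys.time()); msg("call-elements")
    els <- call_elements(blocks, mj$model, mj$tree, rho, params)
    write_bed(els, el_path)
    record("call_elements", el_path, t0)
  } else msg("call-elements: up to date")
  els <- read_bed(el_path)

  # -- stage 5: classify presence + define CNEs -----------------------------
  cne_path <- file.path(out_dir, "cnes.bed")
  mat_path <- file.path(out_dir, "presence.tsv")
  if (!uptodate("define_cnes", list(cne_path, mat_path))) {
    t0 <- as.numeric(Sys.time()); msg("classify + define-cnes")
    states <- classify_presence(els, blocks, genomes, ref = config$ref)
    cnes <- define_cnes(els, ann, states)
    write_bed(cnes, cne_path)
    utils::write.table(data.frame(cne = rownames(states), states,
                                  check.names = FALSE),
                       mat_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    record("define_cnes", list(cne_path, mat_path), t0)
  } else msg("define-cnes: up to date")
  cnes <- read_bed(cne_path)
  pm <- utils::read.table(mat_path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  states <- as.matrix(pm[, -1, drop = FALSE])
  rownames(states) <- pm$cne

  # -- stage 6: losses ------------------------------------------------------
  loss_path <- file.path(out_dir, "losses.tsv")
  syn_path <- file.path(out_dir, "synteny.tsv")
  if (!uptodate("call_losses", list(loss_path, syn_path))) {
    t0 <- as.numeric(Sys.time()); msg("call-losses")
    species <- setdiff(config$tree$tip.label, config$ref)
    synteny <- lapply(species, function(sp)
      gap_free_syntenic_intervals(blocks, genomes[[sp]], sp))
    names(synteny) <- species
    losses <- call_unique_losses(states[cnes$name, , drop = FALSE],
                                 cnes, synteny)
    utils::write.table(losses, loss_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    syn_all <- do.call(rbind, lapply(species, function(sp)
      cbind(species = sp, synteny[[sp]])))
    utils::write.table(syn_all, syn_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    record("call_losses", list(loss_path, syn_path), t0)
  } else msg("call-losses: up to date")
  losses <- utils::read.table(loss_path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)

  # -- stage 7: enrichment --------------------------------------------------
  enr_path <- file.path(out_dir, "enrichment.tsv")
  cnt_path <- file.path(out_dir, "gene_loss_counts.tsv")
  if (!uptodate("enrich", list(enr_path, cnt_path))) {
    t0 <- as.numeric(Sys.time()); msg("enrich")
    tss <- tss_of(ann)
    assign_all <- assign_to_nearest_tss(cnes, tss)
    if (is.null(terms)) {
      set.seed(stage_seed(config$seed, 7L))
      g <- unique(tss$gene_id)
      terms <- data.frame(gene_id = g,
                          term_id = sample(c("termA", "termB"), length(g),
                                           replace = TRUE))
    }
    universe <- unique(assign_all$gene_id[assign_all$assigned])
    lost_cnes <- unique(losses$cne[losses$tier == "high_confidence"])
    sample_genes <- unique(assign_all$gene_id[assign_all$assigned &
                                                assign_all$cne %in% lost_cnes])
    if (length(sample_genes) > 0L) {
      enr <- hypergeometric_enrichment(sample_genes, terms, universe)
    } else {
      enr <- data.frame(term = character(), k = integer(), K = integer(),
                        n = integer(), N = integer(), p = numeric(),
                        q = numeric(), significant = logical())
    }
    utils::write.table(enr, enr_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cnt <- gene_loss_counts(assign_all[assign_all$cne %in% lost_cnes, ,
                                       drop = FALSE])
    utils::write.table(cnt, cnt_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    record("enrich", list(enr_path, cnt_path), t0)
  } else msg("enrich: up to date")

  invisible(manifest)
}
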