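# Shared fixture builders and independent oracles. Everything is generated
# in code at test time; nothing is read from disk except files the tests
# themselves write.

# tiny two-organism annotation written to a temp dir, loaded into a repo
tiny_annotated_repo <- function(seed = 42, n_genes = 10,
                                organisms = c("human", "mouse", "zebrafish")) {
  spec <- simulation_spec(seed = seed, n_genes = n_genes,
                          organisms = organisms, n_planted = min(2, n_genes))
  ann <- make_annotation(spec)
  repo <- repo_create()
  load_annotation(repo, ann$gene_table, ann$transcript_table)
  for (pf in names(ann$probe_maps))
    suppressWarnings(register_platform(repo, pf, ann$probe_maps[[pf]]))
  build_ortholog_index(repo, ann$homolog_table)
  list(repo = repo, ann = ann, spec = spec)
}

# a minimal experiment skeleton: 2 biomaterials, n_case + n_control assays
add_tiny_experiment <- function(repo, platform, n_case = 2, n_control = 2,
                                technology = "microarray",
                                measurement = "gene_expression",
                                organism = "human") {
  exp <- create_experiment(repo, "tiny study", "T. Tester")
  bm1 <- add_biomaterial(repo, organism = organism, cell_type = "L-GMP")
  bm2 <- add_biomaterial(repo, organism = organism, cell_type = "GMP")
  case <- vapply(seq_len(n_case), function(i)
    add_bioassay(repo, exp$id, bm1, measurement, technology, platform), "")
  control <- vapply(seq_len(n_control), function(i)
    add_bioassay(repo, exp$id, bm2, measurement, technology, platform), "")
  list(experiment = exp$id, case = case, control = control,
       biomaterials = c(bm1, bm2))
}

# --- independent oracles -----------------------------------------------------

# brute-force quantile normalization: rank-wise means with tie groups
# averaged over the tied ranks' reference values
qn_oracle <- function(m) {
  n <- nrow(m)
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    for (i in seq_len(n)) {
      ranks_of_tied <- which(sort(x) == x[i])
      out[i, j] <- mean(ref[ranks_of_tied])
    }
  }
  out
}

# brute-force step-up BH: min over j >= i of p_(j) * n / j
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    js <- i:n
    adj[o[i]] <- min(1, min(p[o[js]] * n / js))
  }
  adj
}

# per-read loop FPKM oracle over strand-oriented TSS windows
window_fpkm_oracle <- function(alignments, transcripts, up = 1000,
                               down = 1000) {
  total <- nrow(alignments)
  win_len <- up + down
  vapply(seq_len(nrow(transcripts)), function(i) {
    tx <- transcripts[i, ]
    tss <- if (tx$strand == "+") tx$tx_start else tx$tx_end
    ws <- if (tx$strand == "+") tss - up else tss - down
    we <- if (tx$strand == "+") tss + down else tss + up
    cnt <- 0
    for (r in seq_len(total)) {
      if (alignments$chrom[r] != tx$chrom) next
      mid <- floor((alignments$start[r] + alignments$end[r]) / 2)
      if (mid >= ws && mid < we) cnt <- cnt + 1
    }
    cnt / ((win_len / 1000) * (total / 1e6))
  }, 0)
}

# per-read loop exonic FPKM oracle
transcript_fpkm_oracle <- function(alignments, transcripts) {
  total <- nrow(alignments)
  vapply(seq_len(nrow(transcripts)), function(i) {
    tx <- transcripts[i, ]
    es <- as.integer(strsplit(tx$exon_starts, ",")[[1]])
    ee <- as.integer(strsplit(tx$exon_ends, ",")[[1]])
    cnt <- 0
    for (r in seq_len(total)) {
      if (alignments$chrom[r] != tx$chrom) next
      mid <- floor((alignments$start[r] + alignments$end[r]) / 2)
      if (any(mid >= es & mid < ee)) cnt <- cnt + 1
    }
    cnt / ((sum(ee - es) / 1000) * (total / 1e6))
  }, 0)
}

# per-peak loop assignment oracle: promoter containment first, nearest TSS
# among candidates, lexicographic transcript id tie-break
assign_peaks_oracle <- function(peaks, transcripts, up = 1000, down = 1000) {
  out <- character(nrow(peaks))
  for (p in seq_len(nrow(peaks))) {
    anchor <- if (!is.null(peaks$summit) && !is.na(peaks$summit[p]))
      peaks$summit[p] else floor((peaks$start[p] + peaks$end[p]) / 2)
    cand <- which(transcripts$chrom == peaks$chrom[p])
    if (!length(cand)) { out[p] <- NA_character_; next }
    tss <- ifelse(transcripts$strand[cand] == "+",
                  transcripts$tx_start[cand], transcripts$tx_end[cand])
    ws <- ifelse(transcripts$strand[cand] == "+", tss - up, tss - down)
    we <- ifelse(transcripts$strand[cand] == "+", tss + down, tss + up)
    inside <- anchor >= ws & anchor < we
    pool <- if (any(inside)) which(inside) else seq_along(cand)
    d <- abs(tss[pool] - anchor)
    pick <- pool[order(d, transcripts$transcript_id[cand][pool])][1]
    out[p] <- transcripts$transcript_id[cand][pick]
  }
  out
}

# random annotation-shaped transcript table on one chromosome
random_transcripts <- function(n, chrom = "chrT", span = 200000) {
  tx_start <- sort(sample.int(span - 3000, n))
  len <- sample(500:2500, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  e1 <- pmin(tx_start + pmax(100, len %/% 3), tx_start + len - 1)
  data.frame(
    transcript_id = sprintf("t%03d", seq_len(n)),
    gene_id = sprintf("g%03d", seq_len(n)), chrom = chrom, strand = strand,
    tx_start = tx_start, tx_end = tx_start + len,
    exon_starts = paste(tx_start, e1, sep = ","),
    exon_ends = paste(pmin(e1, tx_start + len), tx_start + len, sep = ","),
    stringsAsFactors = FALSE)
}

random_alignments <- function(n, chrom = "chrT", span = 200000, frag = 150) {
  s <- sample.int(span - frag, n, replace = TRUE)
  data.frame(chrom = chrom, start = s, end = s + frag,
             stringsAsFactors = FALSE)
}
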