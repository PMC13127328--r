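#' Enumerate candidate 30-mer probe targets
#'
#' Splits each gene sequence into all possible k-mers (default k = 30, the
#' padlock-probe target length) and fills in the composition metrics used by
#' the design filters: GC fraction, longest homopolymer run, and the base at
#' the ligation-junction position (1-based position 16 by default).
#'
#' @param genes a \code{Biostrings::DNAStringSet} (names are gene names) or a
#'   named character vector of uppercase ACGT sequences. Genes shorter than
#'   \code{k} yield zero candidates, never an error; IUPAC ambiguity codes
#'   are a hard error naming gene and position (probes are physical oligos).
#' @param k target length (default 30).
#' @return data.frame with columns \code{gene}, \code{offset} (0-based),
#'   \code{seq30}, \code{gc_fraction}, \code{max_homopolymer},
#'   \code{pos16_base}, list column \code{cross_reactive_with} (empty), and
#'   \code{offtarget_hits} (0), ordered by gene name then offset.
#' @export
enumerateCandidates <- function(genes, k = 30L) {
  stopIfNot(k >= 1L, "k must be >= 1")
  seqs <- if (methods::is(genes, "DNAStringSet")) {
    stats::setNames(as.character(genes), names(genes))
  } else {
    toupper(genes)
  }
  stopIfNot(!is.null(names(seqs)) && all(nzchar(names(seqs))),
            "gene sequences must be named")
  for (g in names(seqs)) {
    bad <- regexpr("[^ACGT]", seqs[[g]])
    if (bad > 0)
      stop("non-ACGT character in gene ", g, " at position ", bad,
           " (ambiguity codes are not allowed in probe targets)",
           call. = FALSE)
  }
  per_gene <- lapply(sort(names(seqs)), function(g) {
    s <- seqs[[g]]
    L <- nchar(s)
    if (L < k) return(NULL)
    off <- 0:(L - k)
    kmers <- substring(s, off + 1L, off + k)
    data.frame(gene = g, offset = off, seq30 = kmers)
  })
  out <- do.call(rbind, per_gene)
  if (is.null(out))
    out <- data.frame(gene = character(), offset = integer(),
                      seq30 = character())
  out$gc_fraction <- if (nrow(out))
    vapply(strsplit(out$seq30, ""), function(b) mean(b %in% c("G", "C")),
           numeric(1)) else numeric()
  out$max_homopolymer <- if (nrow(out))
    vapply(strsplit(out$seq30, ""), function(b) max(rle(b)$lengths),
           integer(1)) else integer()
  out$pos16_base <- if (nrow(out)) substr(out$seq30, 16L, 16L) else character()
  out$cross_reactive_with <- replicate(nrow(out), character(), simplify = FALSE)
  out$offtarget_hits <- rep(0L, nrow(out))
  rownames(out) <- NULL
  out
}

#' Padlock composition filter
#'
#' Pure predicate over candidate 30-mers encoding the padlock design
#' criteria: GC content between \code{gc_min} and \code{gc_max} (inclusive),
#' no homopolymer run longer than \code{max_run} (so by default four or more
#' repeated bases fail), and G or C at the ligation-junction position
#' (1-based position 16).
#'
#' @param candidates data.frame from \code{\link{enumerateCandidates}}.
#' @param gc_min,gc_max inclusive GC-fraction bounds (defaults 0.40, 0.60).
#' @param max_run maximum allowed homopolymer run length (default 3).
#' @return the input with logical column \code{comp_pass} and list column
#'   \code{comp_reasons} (subsets of \code{gc_low}, \code{gc_high},
#'   \code{homopolymer}, \code{pos16}).
#' @export
compositionFilter <- function(candidates, gc_min = 0.40, gc_max = 0.60,
                              max_run = 3L) {
  reasons <- lapply(seq_len(nrow(candidates)), function(i) {
    r <- character()
    if (candidates$gc_fraction[i] < gc_min) r <- c(r, "gc_low")
    if (candidates$gc_fraction[i] > gc_max) r <- c(r, "gc_high")
    if (candidates$max_homopolymer[i] > max_run) r <- c(r, "homopolymer")
    if (!candidates$pos16_base[i] %in% c("G", "C")) r <- c(r, "pos16")
    r
  })
  candidates$comp_pass <- lengths(reasons) == 0L
  candidates$comp_reasons <- reasons
  candidates
}

# gapless seed-and-extend identity between two equal-length k-mers at a
# relative shift; identity = matches / k (the full probe length), so partial
# overlaps are penalised
.shiftIdentity <- function(s1, s2, shift, k) {
  # align s1[i] to s2[i + shift]
  i1 <- max(1L, 1L - shift):min(k, k - shift)
  if (length(i1) == 0L) return(0)
  b1 <- substring(s1, i1[1], i1[length(i1)])
  b2 <- substring(s2, i1[1] + shift, i1[length(i1)] + shift)
  sum(strsplit(b1, "")[[1]] == strsplit(b2, "")[[1]]) / k
}

#' Cross-reactivity screen within the gene family
#'
#' Flags candidates whose 30-mer aligns to a 30-mer of another gene at high
#' identity, so a probe would not discriminate the two genes. The screen is
#' an exact-seed (length \code{seed_len}) and gapless-extension scan over all
#' candidate pairs from different genes; identity is matches over the full
#' 30-mer, and candidates reaching \code{min_identity} (default 0.80, i.e.
#' 24/30) are annotated with the offending genes in
#' \code{cross_reactive_with}. Flagged candidates are kept, not deleted.
#'
#' @param candidates data.frame from \code{\link{enumerateCandidates}}.
#' @param min_identity identity threshold in [0, 1].
#' @param seed_len exact shared-seed length triggering extension (default 12).
#' @return the input with \code{cross_reactive_with} populated.
#' @export
uniquenessScreen <- function(candidates, min_identity = 0.80, seed_len = 12L) {
  n <- nrow(candidates)
  if (n == 0L) return(candidates)
  k <- nchar(candidates$seq30[1])
  cross <- replicate(n, character(), simplify = FALSE)
  # index: seed kmer -> (candidate index, position)
  seeds <- lapply(seq_len(n), function(i) {
    s <- candidates$seq30[i]
    pos <- 1:(k - seed_len + 1L)
    data.frame(i = i, pos = pos, seed = substring(s, pos, pos + seed_len - 1L))
  })
  seeds <- do.call(rbind, seeds)
  by_seed <- split(seeds[, c("i", "pos")], seeds$seed)
  checked <- new.env(parent = emptyenv())
  for (grp in by_seed) {
    if (length(unique(candidates$gene[grp$i])) < 2L) next
    for (a in seq_len(nrow(grp) - 1L)) for (b in (a + 1L):nrow(grp)) {
      ia <- grp$i[a]; ib <- grp$i[b]
      if (candidates$gene[ia] == candidates$gene[ib]) next
      shift <- grp$pos[b] - grp$pos[a]
      key <- paste(min(ia, ib), max(ia, ib), shift * sign(ib - ia))
      if (!is.null(checked[[key]])) next
      assign(key, TRUE, envir = checked)
      idt <- .shiftIdentity(candidates$seq30[ia], candidates$seq30[ib],
                            shift, k)
      if (idt >= min_identity) {
        cross[[ia]] <- union(cross[[ia]], candidates$gene[ib])
        cross[[ib]] <- union(cross[[ib]], candidates$gene[ia])
      }
    }
  }
  candidates$cross_reactive_with <- cross
  candidates
}

#' Transcriptome off-target screen
#'
#' Counts, per candidate, the transcriptome records (excluding TCR records,
#' matched by id prefix) containing a gapless match to the 30-mer or its
#' reverse complement at identity at or above \code{min_identity}
#' (Hamming distance at most \code{floor(k (1 - min_identity))}). Records
#' containing IUPAC ambiguity codes are skipped; their number is attached as
#' attribute \code{n_ambiguous_skipped}.
#'
#' @param candidates data.frame from \code{\link{enumerateCandidates}}.
#' @param transcriptome \code{DNAStringSet} or named character vector of
#'   transcript sequences; an empty transcriptome yields zero hits.
#' @param min_identity identity threshold (default 0.80).
#' @param tcr_prefixes id prefixes identifying TCR records to exclude
#'   (default \code{"TR"}).
#' @return the input with \code{offtarget_hits} populated.
#' @export
transcriptomeScreen <- function(candidates, transcriptome,
                                min_identity = 0.80, tcr_prefixes = "TR") {
  if (nrow(candidates) == 0L) return(candidates)
  tx <- if (methods::is(transcriptome, "DNAStringSet")) {
    stats::setNames(as.character(transcriptome), names(transcriptome))
  } else toupper(transcriptome)
  if (length(tx) == 0L) { candidates$offtarget_hits <- 0L; return(candidates) }
  is_tcr <- Reduce(`|`, lapply(tcr_prefixes, function(p)
    startsWith(names(tx), p)))
  tx <- tx[!is_tcr]
  ambiguous <- grepl("[^ACGT]", tx)
  n_skip <- sum(ambiguous)
  if (n_skip > 0) tx <- tx[!ambiguous]
  attr(candidates, "n_ambiguous_skipped") <- n_skip
  if (length(tx) == 0L) { candidates$offtarget_hits <- 0L; return(candidates) }
  subj <- Biostrings::DNAStringSet(unname(tx))
  k <- nchar(candidates$seq30[1])
  max_mm <- floor(k * (1 - min_identity) + 1e-9)
  hits <- vapply(candidates$seq30, function(s) {
    pat <- Biostrings::DNAString(s)
    fwd <- Biostrings::vcountPattern(pat, subj, max.mismatch = max_mm)
    rev <- Biostrings::vcountPattern(Biostrings::reverseComplement(pat),
                                     subj, max.mismatch = max_mm)
    sum(fwd + rev > 0)
  }, numeric(1), USE.NAMES = FALSE)
  candidates$offtarget_hits <- as.integer(hits)
  candidates
}

#' Design a per-gene(-group) probe target panel
#'
#' Runs the full target-design chain in order: enumerate all 30-mers,
#' cross-reactivity screen within the input gene family, padlock composition
#' filter, and (optionally) transcriptome off-target screen. For each gene up
#' to \code{targets_per_gene} best surviving candidates are selected, ranked
#' by: no cross-reactivity or off-target flags first, then GC closest to
#' 50\%, then smallest offset. Genes whose every surviving candidate is
#' cross-reactive only within a fixed set of same-chain/segment genes are
#' merged into a gene group sharing targets (probes cannot discriminate the
#' members); genes with no surviving candidate are reported untargetable,
#' never silently dropped.
#'
#' @param genes named sequences as for \code{\link{enumerateCandidates}}.
#' @param transcriptome optional transcriptome for the off-target screen.
#' @param k target length (default 30).
#' @param gc_min,gc_max,max_run composition parameters.
#' @param min_identity cross-reactivity/off-target identity threshold.
#' @param targets_per_gene targets kept per gene or group (default 3).
#' @return a \linkS4class{DesignReport}.
#' @export
designPanel <- function(genes, transcriptome = NULL, k = 30L,
                        gc_min = 0.40, gc_max = 0.60, max_run = 3L,
                        min_identity = 0.80, targets_per_gene = 3L) {
  cand <- enumerateCandidates(genes, k = k)
  cand <- uniquenessScreen(cand, min_identity = min_identity)
  cand <- compositionFilter(cand, gc_min = gc_min, gc_max = gc_max,
                            max_run = max_run)
  if (!is.null(transcriptome) && length(transcriptome))
    cand <- transcriptomeScreen(cand, transcriptome,
                                min_identity = min_identity)
  gene_names <- sort(unique(if (methods::is(genes, "DNAStringSet"))
    names(genes) else names(genes)))
  unflagged <- lengths(cand$cross_reactive_with) == 0L
  clean <- unflagged & cand$comp_pass
  final <- clean & cand$offtarget_hits == 0L

  perGene <- do.call(rbind, lapply(gene_names, function(g) {
    idx <- cand$gene == g
    data.frame(gene = g,
               n_candidates = sum(idx),
               n_after_uniqueness = sum(idx & unflagged),
               n_after_composition = sum(idx & clean),
               n_after_transcriptome = sum(idx & final))
  }))

  # survivors: composition + transcriptome pass (cross-reactive ones kept for
  # the grouping decision)
  surv <- cand$comp_pass & cand$offtarget_hits == 0L

  rankSelect <- function(idx, n_top) {
    d <- cand[idx, , drop = FALSE]
    flags <- lengths(d$cross_reactive_with) > 0L | d$offtarget_hits > 0L
    ord <- order(flags, abs(d$gc_fraction - 0.5), d$offset, d$gene)
    d[utils::head(ord, n_top), , drop = FALSE]
  }

  chain_seg <- parseGeneName(gene_names)
  unique_genes <- gene_names[vapply(gene_names, function(g)
    any(cand$gene == g & surv & unflagged), logical(1))]
  no_surv <- gene_names[vapply(gene_names, function(g)
    !any(cand$gene == g & surv), logical(1))]
  groupable <- setdiff(gene_names, c(unique_genes, no_surv))

  # union-find over cross-reactivity partners restricted to groupable genes
  parent <- stats::setNames(gene_names, gene_names)
  findRoot <- function(g) { while (parent[[g]] != g) g <- parent[[g]]; g }
  unite <- function(a, b) { parent[[findRoot(a)]] <<- findRoot(b) }
  untargetable <- no_surv
  for (g in groupable) {
    partners <- unique(unlist(cand$cross_reactive_with[cand$gene == g & surv]))
    info_g <- chain_seg[chain_seg$name == toupper(g), ]
    known <- partners[partners %in% gene_names]
    same_class <- vapply(known, function(p) {
      ip <- chain_seg[chain_seg$name == toupper(p), ]
      ip$chain == info_g$chain && ip$segment == info_g$segment
    }, logical(1))
    if (length(known) && all(same_class)) {
      for (p in known) unite(g, p)
    } else {
      untargetable <- c(untargetable, g)  # cross-reactive beyond its class
    }
  }
  groupable <- setdiff(groupable, untargetable)
  roots <- vapply(groupable, findRoot, character(1))
  merged <- split(groupable, roots)

  groups_rows <- list(); targets <- list()
  for (g in unique_genes) {
    groups_rows[[g]] <- data.frame(group_name = g, member_gene = g)
    sel <- rankSelect(which(cand$gene == g & surv & unflagged),
                      targets_per_gene)
    if (nrow(sel)) { sel$group_name <- g; targets[[g]] <- sel }
  }
  for (ms in merged) {
    members <- sort(unique(ms))
    gname <- paste(members, collapse = "/")
    groups_rows[[gname]] <- data.frame(group_name = gname,
                                       member_gene = members)
    in_group <- cand$gene %in% members & surv &
      vapply(cand$cross_reactive_with, function(cr)
        all(cr %in% members), logical(1))
    sel <- rankSelect(which(in_group), targets_per_gene)
    if (nrow(sel)) { sel$group_name <- gname; targets[[gname]] <- sel }
  }
  groups <- if (length(groups_rows)) do.call(rbind, groups_rows) else
    data.frame(group_name = character(), member_gene = character())
  rownames(groups) <- NULL
  tg <- if (length(targets)) do.call(rbind, targets) else
    cand[0, , drop = FALSE]
  rownames(tg) <- NULL
  methods::new("DesignReport", perGene = perGene, targets = tg,
               groups = groups, untargetable = sort(unique(untargetable)),
               params = list(k = k, gc_min = gc_min, gc_max = gc_max,
                             max_run = max_run, min_identity = min_identity,
                             targets_per_gene = targets_per_gene))
}

setMethod("show", "DesignReport", function(object) {
  cat("DesignReport:", nrow(object@perGene), "genes,",
      length(unique(object@groups$group_name)), "groups,",
      nrow(object@targets), "selected targets,",
      length(object@untargetable), "untargetable\n")
})

#' Write design outputs as TSV
#'
#' Writes \code{targets.tsv} (group, gene, 0-based half-open interval,
#' sequence, composition, flags) and \code{design_report.tsv} (per-gene
#' survivor counts) into a directory.
#'
#' @param report a \linkS4class{DesignReport}.
#' @param dir output directory.
#' @export
writeDesignReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tg <- report@targets
  if (nrow(tg)) {
    out <- data.frame(gene_group = tg$group_name, gene = tg$gene,
                      start = tg$offset, end = tg$offset + report@params$k,
                      seq30 = tg$seq30, gc = tg$gc_fraction,
                      pos16 = tg$pos16_base,
                      cross_reactive = vapply(tg$cross_reactive_with,
                                              paste, character(1),
                                              collapse = ","),
                      offtarget_hits = tg$offtarget_hits)
  } else out <- data.frame()
  utils::write.table(out, file.path(dir, "targets.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(report@perGene, file.path(dir, "design_report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
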