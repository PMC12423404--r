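#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of two dosage vectors over pairwise-complete
#' samples.
#'
#' @param d1,d2 Dosage vectors over the same samples.
#' @return r-squared in [0, 1]; `NA` if either vector is constant on the
#'   complete pairs.
#' @export
ld_r2 <- function(d1, d2) {
  stopifnot(length(d1) == length(d2))
  ok <- !is.na(d1) & !is.na(d2)
  if (sum(ok) < 2L) return(NA_real_)
  r <- suppressWarnings(stats::cor(d1[ok], d2[ok]))
  if (is.na(r)) return(NA_real_)
  min(r^2, 1)
}

#' Greedy LD clumping of association results
#'
#' PLINK-style greedy clumping: restrict to variants below the p-value
#' threshold, iterate in ascending p order (ties broken by position then
#' id). A variant founds a new clump unless it lies within `window_bp` of
#' an existing index *and* has r-squared at least `r2_threshold` with it
#' (window measured index-to-variant); otherwise it joins the
#' smallest-p index satisfying both conditions. A variant within the
#' window of an index but below the r-squared threshold founds its own
#' clump.
#'
#' @param results GWAS result data frame (`chrom`, `pos`, `id`, and the
#'   p-value column named by `p_col`).
#' @param genos [genotype_matrix()] holding every variant in `results`.
#' @param p_threshold Significance threshold for clump membership.
#' @param r2_threshold LD threshold (default 0.1).
#' @param window_bp Physical window (default 250 kb).
#' @param p_col Name of the p-value column (default `"p"`).
#' @return List of clumps: each has `chrom`, `index_id`, `index_pos`,
#'   `min_p`, `members` (data frame of member id/pos/p), `start`, `end`.
#' @export
clump <- function(results, genos, p_threshold = 5e-8, r2_threshold = 0.1,
                  window_bp = 250000L, p_col = "p") {
  missing_ids <- setdiff(results$id, genos$variants$id)
  if (length(missing_ids)) {
    stop("variants in results missing from genotypes: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  sig <- results[!is.na(results[[p_col]]) & results[[p_col]] < p_threshold, ,
                 drop = FALSE]
  if (nrow(sig) == 0L) return(list())
  sig <- sig[order(sig[[p_col]], sig$pos, sig$id), , drop = FALSE]
  G <- genos$dosages
  idx_rows <- integer(0)              # rows of sig that are clump indices
  assignment <- integer(nrow(sig))    # clump number per row
  for (i in seq_len(nrow(sig))) {
    joined <- FALSE
    for (k in seq_along(idx_rows)) {
      ir <- idx_rows[k]
      if (sig$chrom[i] != sig$chrom[ir]) next
      if (abs(sig$pos[i] - sig$pos[ir]) > window_bp) next
      r2 <- ld_r2(G[, sig$id[i]], G[, sig$id[ir]])
      if (!is.na(r2) && r2 >= r2_threshold) {
        assignment[i] <- k          # indices scanned in ascending-p order,
        joined <- TRUE              # so the first hit is the best-p index
        break
      }
    }
    if (!joined) {
      idx_rows <- c(idx_rows, i)
      assignment[i] <- length(idx_rows)
    }
  }
  lapply(seq_along(idx_rows), function(k) {
    rows <- sig[assignment == k, , drop = FALSE]
    ir <- sig[idx_rows[k], , drop = FALSE]
    list(chrom = ir$chrom, index_id = ir$id, index_pos = ir$pos,
         min_p = min(rows[[p_col]]),
         members = data.frame(id = rows$id, pos = rows$pos,
                              p = rows[[p_col]], stringsAsFactors = FALSE),
         start = min(rows$pos), end = max(rows$pos))
  })
}

#' Merge clumps whose member spans lie within a gap
#'
#' Union-find style merging per chromosome: clumps whose member spans are
#' within `gap_bp` of each other (or overlap) coalesce, transitively, into
#' one locus. Locus bounds are the min/max member positions; the index is
#' the overall minimum-p member.
#'
#' @param clumps Output of [clump()].
#' @param gap_bp Maximum span-to-span gap to merge (default 250 kb).
#' @param source Optional `(outcome, subgroup)` tag stored on each locus.
#' @return Data frame of loci: `chrom`, `start`, `end`, `index_id`,
#'   `index_pos`, `min_p`, `n_members`, `members` (list column of id
#'   vectors), `source`.
#' @export
merge_clumps <- function(clumps, gap_bp = 250000L, source = NA_character_) {
  if (length(clumps) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      index_id = character(), index_pos = integer(),
                      min_p = numeric(), n_members = integer(),
                      source = character(), stringsAsFactors = FALSE))
  }
  df <- data.frame(chrom = vapply(clumps, `[[`, "", "chrom"),
                   start = vapply(clumps, `[[`, 0, "start"),
                   end = vapply(clumps, `[[`, 0, "end"),
                   stringsAsFactors = FALSE)
  out <- list()
  for (ch in unique(df$chrom)) {
    rows <- which(df$chrom == ch)
    rows <- rows[order(df$start[rows])]
    grp <- list(rows[1])
    if (length(rows) > 1L) {
      for (i in rows[-1]) {
        cur <- grp[[length(grp)]]
        if (df$start[i] - max(df$end[cur]) <= gap_bp) {
          grp[[length(grp)]] <- c(cur, i)
        } else {
          grp[[length(grp) + 1L]] <- i
        }
      }
    }
    for (g in grp) {
      members <- do.call(rbind, lapply(clumps[g], `[[`, "members"))
      imin <- which.min(members$p)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = min(members$pos), end = max(members$pos),
        index_id = members$id[imin], index_pos = members$pos[imin],
        min_p = members$p[imin], n_members = nrow(members),
        source = source, stringsAsFactors = FALSE)
      out[[length(out)]]$members <- I(list(members$id))
    }
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Extend loci and merge overlapping extended intervals
#'
#' Pads each locus by `pad_bp` on both sides (start floored at 1), then
#' merges extended intervals that overlap by at least 1 bp, so the row
#' count is the number of independent loci.
#'
#' @param loci Data frame from [merge_clumps()] (or any frame with
#'   `chrom`, `start`, `end`, `min_p`, `index_id`, `index_pos`).
#' @param pad_bp Extension on each side (default 250 kb).
#' @return Data frame of merged extended intervals with `chrom`, `start`,
#'   `end`, `min_p`, `index_id`, `index_pos`, `n_merged_from`.
#' @export
extend_loci <- function(loci, pad_bp = 250000L) {
  if (nrow(loci) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      min_p = numeric(), index_id = character(),
                      index_pos = integer(), n_merged_from = integer(),
                      stringsAsFactors = FALSE))
  }
  ext <- loci
  ext$start <- pmax(1, ext$start - pad_bp)
  ext$end <- ext$end + pad_bp
  out <- list()
  for (ch in unique(ext$chrom)) {
    rows <- which(ext$chrom == ch)
    rows <- rows[order(ext$start[rows])]
    cur <- rows[1]
    flush <- function(cur) {
      imin <- cur[which.min(ext$min_p[cur])]
      data.frame(chrom = ch, start = min(ext$start[cur]), end = max(ext$end[cur]),
                 min_p = ext$min_p[imin], index_id = ext$index_id[imin],
                 index_pos = ext$index_pos[imin], n_merged_from = length(cur),
                 stringsAsFactors = FALSE)
    }
    if (length(rows) > 1L) {
      for (i in rows[-1]) {
        if (ext$start[i] <= max(ext$end[cur])) {
          cur <- c(cur, i)
        } else {
          out[[length(out) + 1L]] <- flush(cur)
          cur <- i
        }
      }
    }
    out[[length(out) + 1L]] <- flush(cur)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Flag loci overlapping known intervals
#'
#' A locus is flagged known when its interval intersects any known
#' interval on the same chromosome (1-based inclusive coordinates; use
#' [read_bed()] to convert BED half-open input).
#'
#' @param loci Data frame with `chrom`, `start`, `end`.
#' @param known Data frame with `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @return Logical vector: `TRUE` = known, `FALSE` = novel.
#' @export
overlap_known <- function(loci, known) {
  if (nrow(loci) == 0L) return(logical(0))
  if (is.null(known) || nrow(known) == 0L) return(rep(FALSE, nrow(loci)))
  vapply(seq_len(nrow(loci)), function(i) {
    k <- known[known$chrom == loci$chrom[i], , drop = FALSE]
    any(k$start <= loci$end[i] & k$end >= loci$start[i])
  }, logical(1))
}

#' Nearest protein-coding gene to a position
#'
#' Distance is 0 inside a gene span, otherwise the smaller of the
#' distances to the two span ends. Ties go to the gene with the smaller
#' start, then the lexicographically smaller symbol.
#'
#' @param chrom,pos Query position (1-based).
#' @param genes Annotation data frame with `chrom`, `start`, `end`,
#'   `symbol`, and optionally `biotype` (restricted to
#'   `"protein_coding"` when present).
#' @return One-row data frame: `symbol`, `distance` (`NA`/`Inf` when no
#'   gene lies on the chromosome).
#' @export
nearest_gene <- function(chrom, pos, genes) {
  if ("biotype" %in% names(genes)) {
    genes <- genes[genes$biotype == "protein_coding", , drop = FALSE]
  }
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0L) {
    return(data.frame(symbol = NA_character_, distance = Inf,
                      stringsAsFactors = FALSE))
  }
  d <- ifelse(pos >= g$start & pos <= g$end, 0,
              pmin(abs(pos - g$start), abs(pos - g$end)))
  g <- g[order(d, g$start, g$symbol), , drop = FALSE]
  data.frame(symbol = g$symbol[1], distance = sort(d)[1],
             stringsAsFactors = FALSE)
}
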