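# SNP -> binding-site pipeline: matching, motif selection, window folding,
# affinity ratios, and the distance / asymmetry statistics.

#' Middle of a binding-site interval
#'
#' `floor((start0 + end0) / 2)` in 0-based coordinates, returned 1-based;
#' for a site read from BED as `[start, end]` (1-based inclusive) this is
#' `floor((start - 1 + end) / 2) + 1`.
#'
#' @param start,end 1-based inclusive interval.
#' @return 1-based position of the site middle.
#' @export
site_middle <- function(start, end) (start - 1L + end) %/% 2L + 1L

#' Match SNPs to nearby binding sites
#'
#' A (SNP, site) pair is a candidate when they share a transcript and the
#' SNP lies within `radius` bases (inclusive) of the site middle. A SNP
#' near several sites is paired with the nearest only; ties go to the site
#' with the smaller start.
#'
#' @param snps Data.frame with columns `transcript_id`, `pos` (1-based),
#'   `ref`, `alt` (see [read_snps()]).
#' @param sites Data.frame with columns `transcript_id`, `start`, `end`
#'   (1-based inclusive; see [read_sites()]).
#' @param radius Maximum |SNP - site middle| distance in nt (default 40).
#' @return Data.frame of candidates (SNP columns plus `site_start`,
#'   `site_end`, `site_middle`), with attribute `n_unmatched` (SNPs with
#'   no site within the radius).
#' @export
match_snps_to_sites <- function(snps, sites, radius = 40) {
  stopifnot(all(c("transcript_id", "pos", "ref", "alt") %in% names(snps)),
            all(c("transcript_id", "start", "end") %in% names(sites)))
  sites <- sites[order(sites$transcript_id, sites$start), , drop = FALSE]
  mids <- site_middle(sites$start, sites$end)
  idx_by_tx <- split(seq_len(nrow(sites)), sites$transcript_id)
  n <- nrow(snps)
  hit <- integer(n)  # row in `sites`, 0 = unmatched
  for (i in seq_len(n)) {
    rows <- idx_by_tx[[snps$transcript_id[i]]]
    if (is.null(rows)) next
    d <- abs(snps$pos[i] - mids[rows])
    j <- which.min(d)  # ties -> first, i.e. smaller start
    if (d[j] <= radius) hit[i] <- rows[j]
  }
  keep <- hit > 0L
  res <- data.frame(transcript_id = snps$transcript_id[keep],
                    pos = snps$pos[keep], ref = snps$ref[keep],
                    alt = snps$alt[keep],
                    site_start = sites$start[hit[keep]],
                    site_end = sites$end[hit[keep]],
                    site_middle = mids[hit[keep]],
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "n_unmatched") <- sum(!keep)
  res
}

#' Highest-affinity motif within a binding site
#'
#' Scans every k-mer window fully inside the site interval and returns the
#' one with the smallest K_D in the affinity table; ties go to the
#' leftmost window.
#'
#' @param site_start,site_end Site interval (1-based inclusive).
#' @param transcript_seq Transcript sequence.
#' @param table An [affinity_table()].
#' @return List with `start` (1-based motif start), `center`
#'   (`start + floor(k/2)`) and `kmer`, or `NULL` when the site is shorter
#'   than k.
#' @export
select_best_motif <- function(site_start, site_end, transcript_seq,
                              table) {
  k <- attr(table, "k")
  site_end <- as.integer(min(site_end, nchar(transcript_seq)))
  site_start <- as.integer(max(site_start, 1L))
  if (site_end - site_start + 1L < k) return(NULL)
  win <- substr(transcript_seq, site_start, site_end)
  kmers <- seq_kmers(win, k)
  kd <- unclass(table)[kmer_indices(kmers, k)]
  j <- unname(which.min(kd))  # ties -> leftmost
  start <- site_start + j - 1L
  list(start = start, center = start + k %/% 2L, kmer = kmers[j])
}

#' Extract a fold window centred on a motif
#'
#' Window `[center - (L-1)/2, center + (L-1)/2]`. Windows overrunning
#' either transcript end are rejected (`NULL`), never truncated, so every
#' folded window has the same length.
#'
#' @param transcript_seq Transcript sequence.
#' @param center 1-based window center.
#' @param L Odd window length.
#' @return List with `seq` and `offset` (window position =
#'   transcript position - offset), or `NULL` if the window does not fit.
#' @export
extract_window <- function(transcript_seq, center, L) {
  if (L %% 2L != 1L) stop("`L` must be odd", call. = FALSE)
  center <- as.integer(center)
  h <- (as.integer(L) - 1L) %/% 2L
  start <- center - h
  end <- center + h
  if (start < 1L || end > nchar(transcript_seq)) return(NULL)
  list(seq = substr(transcript_seq, start, end), offset = start - 1L)
}

fold_change_stratum <- function(fold_change) {
  cut(fold_change, breaks = c(-Inf, 2, 3, Inf), right = FALSE,
      labels = c("<2", "2-3", ">=3"))
}

#' Affinity ratios for matched SNP/site candidates
#'
#' For every candidate pair: select the best motif in the site, extract an
#' `L`-nt window centred on the motif, verify the reference allele against
#' the transcript, fold both alleles and form the affinity ratio
#' K_eff(alt) / K_eff(ref). Records whose window overruns a transcript
#' end, whose site is shorter than the footprint, or whose reference
#' allele mismatches the transcript are skipped and counted.
#'
#' @param candidates Output of [match_snps_to_sites()].
#' @param transcripts Named character vector of transcript sequences.
#' @param table An [affinity_table()].
#' @param model An [energy_model()].
#' @param L Odd fold-window length (default 201).
#' @param mode `"ensemble"` or `"single_site"` (see [effective_kd()]).
#' @return Data.frame with one row per surviving candidate: identifiers,
#'   `motif_start`, `motif_center`, `distance` (SNP - motif center, nt;
#'   negative = upstream), `K_ref_nM`, `K_alt_nM`, `ratio`,
#'   `fold_change`, `stratum`; attribute `skips` (named counts).
#' @export
compute_snp_effects <- function(candidates, transcripts, table,
                                model = energy_model(), L = 201,
                                mode = c("ensemble", "single_site")) {
  mode <- match.arg(mode)
  skips <- c(unknown_transcript = 0L, short_site = 0L,
             window_edge = 0L, ref_mismatch = 0L)
  nc <- nrow(candidates)
  keep <- logical(nc)
  motif_start <- motif_center <- window_start <- integer(nc)
  k_ref <- k_alt <- numeric(nc)
  tx_pos <- candidates$pos
  tx_idx <- match(candidates$transcript_id, names(transcripts))
  for (i in seq_len(nc)) {
    tx <- if (is.na(tx_idx[i])) NULL else transcripts[[tx_idx[i]]]
    if (is.null(tx) || is.na(tx)) {
      skips["unknown_transcript"] <- skips["unknown_transcript"] + 1L
      next
    }
    motif <- select_best_motif(candidates$site_start[i],
                               candidates$site_end[i], tx, table)
    if (is.null(motif)) {
      skips["short_site"] <- skips["short_site"] + 1L
      next
    }
    win <- extract_window(tx, motif$center, L)
    wpos <- if (is.null(win)) NA_integer_ else tx_pos[i] - win$offset
    if (is.null(win) || wpos < 1L || wpos > L) {
      skips["window_edge"] <- skips["window_edge"] + 1L
      next
    }
    if (substr(win$seq, wpos, wpos) != candidates$ref[i]) {
      skips["ref_mismatch"] <- skips["ref_mismatch"] + 1L
      next
    }
    alt_seq <- sub_base(win$seq, wpos, candidates$alt[i])
    site_start_w <- motif$start - win$offset
    keep[i] <- TRUE
    motif_start[i] <- motif$start
    motif_center[i] <- motif$center
    window_start[i] <- win$offset + 1L
    k_ref[i] <- effective_kd(win$seq, table, model, mode, site_start_w)
    k_alt[i] <- effective_kd(alt_seq, table, model, mode, site_start_w)
  }
  if (any(keep)) {
    ratio <- k_alt[keep] / k_ref[keep]
    fc <- pmax(ratio, 1 / ratio)
    res <- data.frame(
      transcript_id = candidates$transcript_id[keep],
      pos = tx_pos[keep], ref = candidates$ref[keep],
      alt = candidates$alt[keep],
      site_start = candidates$site_start[keep],
      site_end = candidates$site_end[keep],
      motif_start = motif_start[keep], motif_center = motif_center[keep],
      distance = tx_pos[keep] - motif_center[keep],
      window_start = window_start[keep],
      K_ref_nM = k_ref[keep], K_alt_nM = k_alt[keep], ratio = ratio,
      fold_change = fc, stringsAsFactors = FALSE)
  } else res <- empty_effects()
  res$stratum <- as.character(fold_change_stratum(res$fold_change))
  rownames(res) <- NULL
  attr(res, "skips") <- skips
  res
}

empty_effects <- function() {
  data.frame(transcript_id = character(0), pos = integer(0),
             ref = character(0), alt = character(0),
             site_start = integer(0), site_end = integer(0),
             motif_start = integer(0), motif_center = integer(0),
             distance = integer(0), window_start = integer(0),
             K_ref_nM = numeric(0), K_alt_nM = numeric(0),
             ratio = numeric(0), fold_change = numeric(0),
             stringsAsFactors = FALSE)
}

#' Structure-mediated SNP effects on protein binding
#'
#' The end-to-end analysis: match SNPs to binding sites, select the
#' highest-affinity motif per site, fold an `L`-nt window around the motif
#' for both alleles, and compute per-SNP affinity ratios. The returned
#' object has `print`, `summary` and `plot` methods; `summary` runs the
#' binomial asymmetry test and the per-stratum distance statistics.
#'
#' @param transcripts Named character vector of transcript sequences (see
#'   [read_fasta()]).
#' @param snps SNP data.frame ([read_snps()]).
#' @param sites Binding-site data.frame ([read_sites()]).
#' @param table An [affinity_table()].
#' @param model An [energy_model()].
#' @param L Odd fold-window length (101, 201 or 401 by convention).
#' @param mode `"ensemble"` or `"single_site"`.
#' @param radius Matching radius around the site middle (nt).
#' @param transcript_allowlist Optional character vector; when given,
#'   SNPs and sites on other transcripts are dropped first (e.g. an
#'   Ensembl canonical-transcript list).
#' @return Object of class `snp_effects`: list with `effects` (see
#'   [compute_snp_effects()]), `skips`, and `params`.
#' @examples
#' co <- gen_cohort(4, seed = 1, L = 101)
#' fit <- snp_binding_effects(co$transcripts, co$snps, co$sites, co$table,
#'                            L = 101)
#' summary(fit)
#' @export
snp_binding_effects <- function(transcripts, snps, sites, table,
                                model = energy_model(), L = 201,
                                mode = c("ensemble", "single_site"),
                                radius = 40,
                                transcript_allowlist = NULL) {
  mode <- match.arg(mode)
  if (!is.null(transcript_allowlist)) {
    snps <- snps[snps$transcript_id %in% transcript_allowlist, ,
                 drop = FALSE]
    sites <- sites[sites$transcript_id %in% transcript_allowlist, ,
                   drop = FALSE]
  }
  cand <- match_snps_to_sites(snps, sites, radius)
  eff <- compute_snp_effects(cand, transcripts, table, model, L, mode)
  skips <- c(n_snps = nrow(snps), n_sites = nrow(sites),
             n_candidates = nrow(cand),
             unmatched = attr(cand, "n_unmatched"),
             attr(eff, "skips"))
  structure(list(effects = eff, skips = skips,
                 params = list(L = L, mode = mode, radius = radius,
                               model = model, k = attr(table, "k"))),
            class = "snp_effects")
}

#' @export
print.snp_effects <- function(x, ...) {
  cat(sprintf(paste0("SNP binding effects: %d records (window %d nt, ",
                     "%s mode, footprint %d nt)\n"),
              nrow(x$effects), x$params$L, x$params$mode, x$params$k))
  sk <- x$skips
  cat(sprintf("  %d SNPs, %d sites -> %d candidates; skips: %s\n",
              sk[["n_snps"]], sk[["n_sites"]], sk[["n_candidates"]],
              paste(names(sk)[-(1:3)], sk[-(1:3)], sep = "=",
                    collapse = ", ")))
  if (nrow(x$effects) > 0) {
    cat(sprintf("  ratio range %.4g - %.4g; strata: %s\n",
                min(x$effects$ratio), max(x$effects$ratio),
                paste(names(table(x$effects$stratum)),
                      table(x$effects$stratum), sep = "=",
                      collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.snp_effects <- function(object, ...) {
  eff <- object$effects
  res <- list(
    n = nrow(eff),
    asymmetry = if (any(eff$ratio != 1)) asymmetry_test(object) else NULL,
    strata = table(factor(eff$stratum, levels = c("<2", "2-3", ">=3"))),
    ratio_min = if (nrow(eff)) min(eff$ratio) else NA_real_,
    ratio_max = if (nrow(eff)) max(eff$ratio) else NA_real_,
    skips = object$skips, params = object$params)
  class(res) <- "summary.snp_effects"
  res
}

#' @export
print.summary.snp_effects <- function(x, ...) {
  cat(sprintf("SNP binding effects (window %d nt, %s mode)\n",
              x$params$L, x$params$mode))
  cat(sprintf("  records: %d; ratio min %.4g, max %.4g\n", x$n,
              x$ratio_min, x$ratio_max))
  cat("  fold-change strata: ",
      paste(names(x$strata), as.integer(x$strata), sep = "=",
            collapse = ", "), "\n", sep = "")
  if (!is.null(x$asymmetry)) print(x$asymmetry)
  invisible(x)
}

#' @export
plot.snp_effects <- function(x, type = c("ratios", "distance",
                                         "cumulative"), ...) {
  type <- match.arg(type)
  eff <- x$effects
  if (type == "ratios") {
    hist(log2(eff$ratio), breaks = 50,
         xlab = "log2 affinity ratio (alt/ref)", main = "", ...)
    abline(v = 0, col = "red", lty = 2)
  } else if (type == "distance") {
    hist(eff$distance, breaks = 30,
         xlab = "SNP - motif center distance (nt)", main = "", ...)
    abline(v = 0, col = "red", lty = 2)
  } else {
    cc <- cumulative_ratio_curves(x)
    above <- cc[cc$direction == "above", ]
    below <- cc[cc$direction == "below_reciprocated", ]
    plot(above$value, above$cumulative, type = "s", log = "x",
         xlab = "reciprocated affinity ratio",
         ylab = "cumulative count", col = "blue", ...)
    lines(below$value, below$cumulative, type = "s", col = "darkgreen")
    legend("bottomright", c("ratio > 1", "ratio < 1 (reciprocated)"),
           col = c("blue", "darkgreen"), lwd = 1, bty = "n")
  }
  invisible(x)
}

ratios_of <- function(x) {
  if (inherits(x, "snp_effects")) x$effects$ratio
  else if (is.data.frame(x)) x$ratio
  else stop("cannot extract ratios from this object", call. = FALSE)
}

#' Binomial asymmetry of SNP effect directions
#'
#' Counts affinity ratios strictly above and strictly below 1 (ratios
#' exactly 1 are excluded and reported separately) and tests the null of
#' a 50/50 split with an exact one-sided binomial test toward an excess of
#' ratios > 1 -- the direction in which the alternate allele makes protein
#' binding harder. Also reports the mean ratio above 1, below 1, and
#' overall.
#'
#' Can be called on a [snp_binding_effects()] object, an effects
#' data.frame, or directly on counts via `n_above`/`n_below` (in which
#' case the means are `NA`).
#'
#' @param x A `snp_effects` object, an effects data.frame with a `ratio`
#'   column, or missing when counts are given.
#' @param n_above,n_below Direct counts of ratios above/below 1.
#' @return Object of class `asymmetry_summary`: `n_above`, `n_below`,
#'   `n_ties`, `p_value`, `mean_above`, `mean_below`, `mean_all`.
#' @examples
#' asymmetry_test(n_above = 10, n_below = 10)$p_value  # 0.5881
#' @export
asymmetry_test <- function(x, n_above = NULL, n_below = NULL) {
  if (missing(x) || is.null(x)) {
    stopifnot(!is.null(n_above), !is.null(n_below))
    counts <- c(above = as.integer(n_above), below = as.integer(n_below))
    means <- c(above = NA_real_, below = NA_real_, all = NA_real_)
    ties <- NA_integer_
  } else {
    r <- ratios_of(x)
    if (!length(r)) stop("no effect records", call. = FALSE)
    counts <- c(above = sum(r > 1), below = sum(r < 1))
    ties <- sum(r == 1)
    means <- c(above = mean(r[r > 1]), below = mean(r[r < 1]),
               all = mean(r))
  }
  n <- sum(counts)
  if (n < 1L)
    stop("need at least one ratio different from 1", call. = FALSE)
  p <- pbinom(counts[["above"]] - 1L, n, 0.5, lower.tail = FALSE)
  structure(list(n_above = counts[["above"]], n_below = counts[["below"]],
                 n_ties = ties, p_value = p,
                 mean_above = means[["above"]],
                 mean_below = means[["below"]], mean_all = means[["all"]]),
            class = "asymmetry_summary")
}

#' @export
print.asymmetry_summary <- function(x, ...) {
  cat("Binomial asymmetry of affinity-ratio directions\n")
  cat(sprintf("  ratios > 1: %d, < 1: %d%s\n", x$n_above, x$n_below,
              if (!is.na(x$n_ties) && x$n_ties > 0)
                sprintf(" (%d exactly 1 excluded)", x$n_ties) else ""))
  cat(sprintf("  one-sided exact binomial p = %.4g\n", x$p_value))
  if (!is.na(x$mean_all))
    cat(sprintf("  mean ratio: >1 %.4g, <1 %.4g, all %.4g\n",
                x$mean_above, x$mean_below, x$mean_all))
  invisible(x)
}

#' Distance distributions by effect stratum
#'
#' Histograms of signed SNP-to-motif-center distances, stratified by
#' fold change (<2, 2-3, >=3), with the population standard deviation of
#' each stratum and its bootstrap standard error.
#'
#' @param x A `snp_effects` object or effects data.frame (columns
#'   `distance`, `fold_change`).
#' @param n_boot Bootstrap resamples for the SE of the sd (default 1000).
#' @param seed Seed for the bootstrap.
#' @return List of class `distance_distribution`: `stats` (data.frame
#'   stratum/n/sd/sd_se) and `distances` (named list of distance vectors
#'   per stratum). Empty strata get `NA` sd.
#' @export
distance_distribution <- function(x, n_boot = 1000, seed = 1) {
  eff <- if (inherits(x, "snp_effects")) x$effects else x
  stopifnot(all(c("distance", "fold_change") %in% names(eff)))
  strata <- c("<2", "2-3", ">=3")
  sv <- as.character(fold_change_stratum(eff$fold_change))
  dist_by <- lapply(setNames(strata, strata),
                    function(s) eff$distance[sv == s])
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  stats <- with_seed(seed, {
    do.call(rbind, lapply(strata, function(s) {
      v <- dist_by[[s]]
      if (length(v) == 0)
        return(data.frame(stratum = s, n = 0L, sd = NA_real_,
                          sd_se = NA_real_))
      bs <- replicate(n_boot, pop_sd(v[sample.int(length(v),
                                                  replace = TRUE)]))
      data.frame(stratum = s, n = length(v), sd = pop_sd(v),
                 sd_se = sd(bs))
    }))
  })
  structure(list(stats = stats, distances = dist_by),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat("SNP-to-motif distance spread by fold-change stratum\n")
  s <- x$stats
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-4s n = %6d  sd = %s\n", s$stratum[i], s$n[i],
                if (is.na(s$sd[i])) "undefined (empty stratum)"
                else sprintf("%.2f +/- %.2f nt", s$sd[i], s$sd_se[i])))
  invisible(x)
}

#' Cumulative affinity-ratio curves
#'
#' Ratios below 1 are reciprocated onto [1, Inf) and accumulated
#' separately from ratios naturally above 1, giving the two monotone
#' curves whose separation displays the direction asymmetry. Ratios
#' exactly 1 are excluded.
#'
#' @param x A `snp_effects` object or effects data.frame.
#' @return Data.frame with columns `direction` (`"above"` /
#'   `"below_reciprocated"`), `value` (>= 1, sorted within direction) and
#'   `cumulative` (count of ratios <= value in that direction).
#' @export
cumulative_ratio_curves <- function(x) {
  r <- ratios_of(x)
  ab <- sort(r[r > 1])
  be <- sort(1 / r[r < 1])
  rbind(
    data.frame(direction = rep("above", length(ab)), value = ab,
               cumulative = seq_along(ab)),
    data.frame(direction = rep("below_reciprocated", length(be)),
               value = be, cumulative = seq_along(be)))
}

#' Write pipeline outputs as TSV
#'
#' Writes `effects.tsv` (one record per row; K_D in nM, distances in nt),
#' `summary.tsv` (asymmetry counts/means and p-value) and `report.tsv`
#' (parameters and skip counters) under `dir`. Output is deterministic:
#' identical inputs give byte-identical files.
#'
#' @param x A `snp_effects` object.
#' @param dir Output directory (created if needed).
#' @export
write_snp_effects <- function(x, dir) {
  stopifnot(inherits(x, "snp_effects"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  eff <- x$effects
  num <- vapply(eff, is.double, logical(1))
  eff[num] <- lapply(eff[num], function(v) sprintf("%.10g", v))
  write.table(eff, file.path(dir, "effects.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (nrow(x$effects) && any(x$effects$ratio != 1)) {
    a <- asymmetry_test(x)
    su <- data.frame(n_above = a$n_above, n_below = a$n_below,
                     n_ties = a$n_ties,
                     binomial_p = sprintf("%.10g", a$p_value),
                     mean_above = sprintf("%.10g", a$mean_above),
                     mean_below = sprintf("%.10g", a$mean_below),
                     mean_all = sprintf("%.10g", a$mean_all))
    write.table(su, file.path(dir, "summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  rep <- data.frame(key = c(paste0("skip_", names(x$skips)),
                            "window_L_nt", "mode", "radius_nt",
                            "footprint_nt"),
                    value = c(as.character(x$skips),
                              as.character(x$params$L), x$params$mode,
                              as.character(x$params$radius),
                              as.character(x$params$k)))
  write.table(rep, file.path(dir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
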