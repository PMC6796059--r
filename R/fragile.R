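#' Load a fragile-site catalogue
#'
#' BED4-like tab-separated input (chrom, start, end, name; 0-based
#' half-open, no header). Records are validated, sorted per chromosome,
#' and overlapping records with the same name are merged into one
#' interval.
#'
#' @param path BED file path.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, of
#'   class `fragile_sites`.
#' @export
load_fragile_sites <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 4)
  if (length(bad))
    stop("malformed fragile-site row at line ", bad[1], " of ", path,
         " (need chrom, start, end, name)")
  df <- data.frame(chrom = vapply(parts, `[`, "", 1),
                   start = suppressWarnings(as.numeric(vapply(parts, `[`, "", 2))),
                   end = suppressWarnings(as.numeric(vapply(parts, `[`, "", 3))),
                   name = vapply(parts, `[`, "", 4),
                   stringsAsFactors = FALSE)
  bad <- which(is.na(df$start) | is.na(df$end))
  if (length(bad))
    stop("non-numeric coordinates at line ", bad[1], " of ", path)
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop("start >= end at line ", bad[1], " of ", path)

  merged <- do.call(rbind, lapply(split(df, paste(df$chrom, df$name)), function(g) {
    ir <- IRanges::reduce(IRanges::IRanges(g$start + 1, g$end))
    data.frame(chrom = g$chrom[1], start = IRanges::start(ir) - 1,
               end = IRanges::end(ir), name = g$name[1],
               stringsAsFactors = FALSE)
  }))
  merged <- merged[order(merged$chrom, merged$start, merged$name), ]
  rownames(merged) <- NULL
  class(merged) <- c("fragile_sites", "data.frame")
  merged
}

#' Annotate call breakpoints against fragile sites
#'
#' Every non-terminal endpoint of every call is mapped to its nearest
#' fragile site on the same chromosome: `within` if the breakpoint
#' coordinate (the call's outer bin edge, so resolution is one bin) lies
#' inside the site interval, `proximal` if the nearest site boundary is at
#' most `proximity` bp away, otherwise `none`. Terminal endpoints
#' (chromosome termini) are excluded — they are consequences of the call
#' reaching the end of the chromosome, not breakpoints. Nearest-site ties
#' are broken by sorted order.
#'
#' @param calls calls data.frame with `start_terminal` / `end_terminal`
#'   filled (see [classify_call()] or [read_cnv_table()]).
#' @param sites a `fragile_sites` catalogue.
#' @param proximity proximity radius in bp (default 2.5 Mb).
#' @return data.frame with one row per non-terminal breakpoint: `cell`,
#'   `chrom`, `which_end`, `breakpoint` (bp), `status`, `site`, `distance`.
#' @export
annotate_breakpoints <- function(calls, sites, proximity = 2.5e6) {
  rows <- list()
  for (r in seq_len(nrow(calls))) {
    for (side in c("start", "end")) {
      if (isTRUE(calls[[paste0(side, "_terminal")]][r])) next
      bp <- calls[[side]][r]
      cand <- sites[sites$chrom == calls$chrom[r], , drop = FALSE]
      if (nrow(cand)) {
        within <- cand$start <= bp & bp <= cand$end
        dist <- ifelse(within, 0, pmin(abs(bp - cand$start), abs(bp - cand$end)))
        k <- which.min(dist)  # first minimum = sorted-order tie-break
        d <- dist[k]
        status <- if (d == 0) "within" else if (d <= proximity) "proximal" else "none"
        site <- if (status == "none") "" else cand$name[k]
        if (status == "none") d <- dist[k]
      } else {
        status <- "none"; site <- ""; d <- NA_real_
      }
      rows[[length(rows) + 1]] <- data.frame(
        cell = calls$cell[r], chrom = calls$chrom[r], which_end = side,
        breakpoint = bp, status = status, site = site, distance = d,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(cell = character(), chrom = character(),
                      which_end = character(), breakpoint = numeric(),
                      status = character(), site = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of breakpoints falling within fragile sites
#'
#' @param annotations output of [annotate_breakpoints()].
#' @return List with `n_within`, `n_proximal`, `n_breakpoints` and
#'   `fraction` (= n_within / n_breakpoints; proximal breakpoints are
#'   reported separately, not folded into the numerator).
#' @export
fragile_fraction <- function(annotations) {
  n <- nrow(annotations)
  if (!n) stop("no breakpoints to summarize")
  n_within <- sum(annotations$status == "within")
  n_prox <- sum(annotations$status == "proximal")
  list(n_within = n_within, n_proximal = n_prox, n_breakpoints = n,
       fraction = n_within / n)
}
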