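#' Fusion caller parameters
#'
#' @param min_overhang Minimum aligned bases required on each side of a
#'   junction for a read to support it, nucleotides.
#' @param min_supporting_reads Minimum supporting read pairs for a call.
#' @param k Seed k-mer size of the transcriptome index.
#' @param max_mismatches_per_segment Mismatch budget when extending a seed
#'   chain into an alignment segment.
#' @return A list of class `spet_caller_params`.
#' @export
caller_params <- function(min_overhang = 10L,
                          min_supporting_reads = 2L,
                          k = 21L,
                          max_mismatches_per_segment = 2L) {
  stopifnot(min_overhang >= 1, k >= 11, min_supporting_reads >= 1,
            max_mismatches_per_segment >= 0)
  structure(
    list(
      min_overhang = as.integer(min_overhang),
      min_supporting_reads = as.integer(min_supporting_reads),
      k = as.integer(k),
      max_mismatches_per_segment = as.integer(max_mismatches_per_segment)
    ),
    class = "spet_caller_params"
  )
}

# ---- sequence encoding ------------------------------------------------------

# A=0 C=1 G=2 T=3; anything else NA.
BASE_LOOKUP <- local({
  v <- rep(NA_integer_, 128L)
  v[utf8ToInt("A")] <- 0L; v[utf8ToInt("C")] <- 1L
  v[utf8ToInt("G")] <- 2L; v[utf8ToInt("T")] <- 3L
  v
})

encode_seq <- function(s) {
  BASE_LOOKUP[utf8ToInt(s)]
}

# Rolling k-mer codes of an integer-coded sequence; codes are exact doubles
# (4^k < 2^53 for k <= 26).  Positions 0-based; NA where a window contains a
# non-ACGT base.
kmer_codes_vec <- function(code, k) {
  n <- length(code) - k + 1L
  if (n < 1L) return(numeric(0))
  out <- numeric(n)
  for (j in seq_len(k)) {
    out <- out + code[j:(j + n - 1L)] * 4^(k - j)
  }
  out
}

#' Build an exact k-mer index over a reference transcriptome
#'
#' @param reference Tibble (`transcript_id`, `gene_id`, `seq`) or a FASTA
#'   path readable by [read_reference_fasta()]. Duplicate transcript ids are
#'   an error.
#' @param k K-mer size.
#' @return An object of class `spet_index`. Its `kmers` table maps each
#'   k-mer occurrence to (transcript, 0-based position); `ambiguous` flags
#'   occurrences of k-mers shared by more than one gene.
#' @export
build_reference_index <- function(reference, k = 21L) {
  if (is.character(reference) && length(reference) == 1L) {
    reference <- read_reference_fasta(reference)
  }
  stopifnot(all(c("transcript_id", "gene_id", "seq") %in% names(reference)))
  if (nrow(reference) == 0L) abort("reference transcript set is empty")
  if (anyDuplicated(reference$transcript_id)) {
    abort("duplicate transcript_id in reference")
  }
  k <- as.integer(k)

  codes <- lapply(reference$seq, encode_seq)
  per_tx <- lapply(seq_along(codes), function(i) {
    kc <- kmer_codes_vec(codes[[i]], k)
    keep <- !is.na(kc)
    data.table::data.table(
      code = kc[keep], tx = i, pos = which(keep) - 1L
    )
  })
  tab <- data.table::rbindlist(per_tx)
  data.table::setorder(tab, code, tx, pos)

  gene_of <- reference$gene_id
  # flag k-mers occurring in more than one gene
  ng <- tab[, list(ngene = data.table::uniqueN(gene_of[tx])), by = "code"]
  tab <- ng[tab, on = "code"]
  tab[, `:=`(ambiguous = ngene > 1L, ngene = NULL)]

  ucodes <- unique(tab$code)  # sorted (tab is ordered by code)
  cnt <- tab[, .N, by = "code"]$N
  ends <- cumsum(cnt)
  starts <- ends - cnt + 1L

  structure(
    list(
      k = k,
      reference = as_tibble(reference[, c("transcript_id", "gene_id", "seq")]),
      tx_codes = codes,
      tx_length = nchar(reference$seq),
      kmers = tab,
      ucodes = ucodes,
      ustart = starts,
      uend = ends
    ),
    class = "spet_index"
  )
}

#' @export
print.spet_index <- function(x, ...) {
  cat(
    "<spet_index> k=", x$k, ", ", nrow(x$reference), " transcripts, ",
    nrow(x$kmers), " k-mer occurrences (",
    sum(x$kmers$ambiguous), " ambiguous)\n",
    sep = ""
  )
  invisible(x)
}

# Look up a vector of k-mer codes; returns row-range [s,e] into index$kmers
# (0 length where absent).
index_lookup <- function(index, q) {
  i <- findInterval(q, index$ucodes)
  ok <- !is.na(q) & i > 0L
  ok[ok] <- index$ucodes[i[ok]] == q[ok]
  s <- rep(NA_integer_, length(q))
  e <- rep(NA_integer_, length(q))
  s[ok] <- index$ustart[i[ok]]
  e[ok] <- index$uend[i[ok]]
  list(hit = ok, s = s, e = e)
}

# ---- FASTQ ------------------------------------------------------------------

read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L || n %% 4L != 0L) {
    abort(paste0("malformed FASTQ (", path, "): ", n, " lines, not a multiple of 4"))
  }
  ids <- lines[seq(1L, n, by = 4L)]
  seqs <- lines[seq(2L, n, by = 4L)]
  plus <- lines[seq(3L, n, by = 4L)]
  bad <- which(!startsWith(ids, "@"))
  if (length(bad) > 0L) {
    abort(paste0("malformed FASTQ (", path, ") at line ", (bad[1] - 1L) * 4L + 1L,
                 ": record does not start with @"))
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad) > 0L) {
    abort(paste0("malformed FASTQ (", path, ") at line ", (bad[1] - 1L) * 4L + 3L,
                 ": missing + separator"))
  }
  tibble(read_id = sub("\\s.*$", "", sub("^@", "", ids)), seq = toupper(seqs))
}

# ---- alignment --------------------------------------------------------------

#' Align paired-end reads to the transcriptome index
#'
#' Seed-chain-extend alignment: exact k-mer seeds are chained per
#' (transcript, diagonal), then extended allowing up to
#' `max_mismatches_per_segment` substitutions.  A read whose best
#' explanation is a prefix on one gene plus a suffix on another (together
#' covering all but at most 2 bases) is marked split; reads with equally
#' good placements in more than one gene are dropped as non-unique.  Both
#' read orientations are tried.
#'
#' @param r1,r2 FASTQ paths (or tibbles from an internal reader) for the two
#'   mates. `r2` may be `NULL` for single-end input.
#' @param index A `spet_index`.
#' @param params A [caller_params()].
#' @return An object of class `spet_alignments`: list with `alignments`
#'   (one row per read: status `unique`/`split`/`ambiguous`/`unmapped`,
#'   orientation, segment coordinates in transcript and read space) plus the
#'   read sequences and the reference, which the fusion caller reuses.
#' @export
align_reads <- function(r1, r2 = NULL, index, params = caller_params()) {
  stopifnot(inherits(index, "spet_index"))
  rd1 <- if (is.character(r1)) read_fastq(r1) else r1
  rd1$mate <- "R1"
  rd <- rd1
  if (!is.null(r2)) {
    rd2 <- if (is.character(r2)) read_fastq(r2) else r2
    rd2$mate <- "R2"
    rd <- bind_rows(rd1, rd2)
  }
  if (nrow(rd) == 0L) abort("no reads to align")
  RL <- unique(nchar(rd$seq))
  if (length(RL) != 1L) abort("reads must have uniform length")
  k <- index$k
  if (RL < k) abort("reads shorter than the index k-mer size")

  n <- nrow(rd)
  # integer base codes for both orientations, one matrix per orientation
  enc_fwd <- matrix(BASE_LOOKUP[utf8ToInt(paste(rd$seq, collapse = ""))], nrow = RL)
  rseq_rev <- revcomp(rd$seq)
  enc_rev <- matrix(BASE_LOOKUP[utf8ToInt(paste(rseq_rev, collapse = ""))], nrow = RL)

  cand <- collect_candidates(enc_fwd, enc_rev, index, RL, k)

  nk <- RL - k + 1L
  aln <- decide_alignments(cand, enc_fwd, enc_rev, index, RL, k, nk, params, n)
  aln$read_id <- rd$read_id[aln$read]
  aln$mate <- rd$mate[aln$read]

  structure(
    list(
      alignments = as_tibble(aln)[, c(
        "read_id", "mate", "status", "orientation",
        "tx", "gene", "t_start", "t_end", "r_start", "r_end",
        "tx2", "gene2", "t_start2", "t_end2", "r_start2", "r_end2", "split_pos"
      )],
      reads = rd,
      reference = index$reference,
      read_length = RL,
      params = params
    ),
    class = "spet_alignments"
  )
}

# Bulk k-mer seeding: returns a data.table of seed chains per
# (read, orient, tx, diag) with hit counts and seed read-position range.
collect_candidates <- function(enc_fwd, enc_rev, index, RL, k) {
  nk <- RL - k + 1L
  n <- ncol(enc_fwd)
  out <- vector("list", 2L)
  for (oi in 1:2) {
    enc <- if (oi == 1L) enc_fwd else enc_rev
    K <- matrix(0, nrow = nk, ncol = n)
    for (j in seq_len(k)) {
      K <- K + enc[j:(j + nk - 1L), , drop = FALSE] * 4^(k - j)
    }
    q <- as.vector(K)  # column-major: read-major blocks of nk
    lu <- index_lookup(index, q)
    hit_idx <- which(lu$hit)
    if (length(hit_idx) == 0L) {
      out[[oi]] <- NULL
      next
    }
    reps <- lu$e[hit_idx] - lu$s[hit_idx] + 1L
    rows <- sequence(reps) - 1L + rep(lu$s[hit_idx], reps)
    qi <- rep(hit_idx, reps)
    dt <- data.table::data.table(
      read = ((qi - 1L) %/% nk) + 1L,
      rpos = ((qi - 1L) %% nk),
      tx = index$kmers$tx[rows],
      tpos = index$kmers$pos[rows],
      orient = oi
    )
    out[[oi]] <- dt
  }
  hits <- data.table::rbindlist(out[!vapply(out, is.null, TRUE)])
  if (nrow(hits) == 0L) {
    return(data.table::data.table(
      read = integer(), orient = integer(), tx = integer(), diag = integer(),
      N = integer(), rmin = integer(), rmax = integer()
    ))
  }
  hits[, diag := tpos - rpos]
  hits[, list(N = .N, rmin = min(rpos), rmax = max(rpos)),
       by = c("read", "orient", "tx", "diag")]
}

# Per-position match profile of a read against one (transcript, diagonal):
# in-bounds read interval [lo, hi) and a logical match vector over it.
candidate_profile <- function(rcode, tcode, diag) {
  RL <- length(rcode)
  tl <- length(tcode)
  lo <- max(0L, -diag)             # smallest read pos with in-bounds partner
  hi <- min(RL, tl - diag)         # one past largest
  if (hi <= lo) return(NULL)
  i <- lo:(hi - 1L)
  rb <- rcode[i + 1L]
  tb <- tcode[i + diag + 1L]
  list(lo = lo, hi = hi, match = !(is.na(rb) | is.na(tb) | rb != tb))
}

# Maximal segment around the exact seed run with <= budget mismatches.
# Returns c(r_start, r_end) (0-based half-open) or NULL.
extend_candidate <- function(prof, rmin, rmax, k, budget) {
  if (is.null(prof)) return(NULL)
  lo <- prof$lo; hi <- prof$hi; mism <- !prof$match
  if (sum(mism) <= budget) {
    return(c(lo, hi))
  }
  s <- rmin
  e <- rmax + k       # [s, e) is the exact seed run
  used <- 0L
  repeat {
    grew <- FALSE
    if (s - 1L >= lo) {
      if (!mism[s - lo]) { s <- s - 1L; grew <- TRUE }
      else if (used < budget) { used <- used + 1L; s <- s - 1L; grew <- TRUE }
    }
    if (e < hi) {
      if (!mism[e - lo + 1L]) { e <- e + 1L; grew <- TRUE }
      else if (used < budget) { used <- used + 1L; e <- e + 1L; grew <- TRUE }
    }
    if (!grew) break
  }
  c(s, e)
}

# Best split of a read between candidate A (prefix) and candidate B
# (suffix): the read breakpoint x maximizes matches(A over [loA,x)) +
# matches(B over [x,hiB)), leftmost among maxima, so junction homology is
# resolved to its 5'-most representation.  Each side must fit within the
# per-segment mismatch budget.
split_score <- function(profA, profB, RL, budget) {
  if (is.null(profA) || is.null(profB)) return(NULL)
  if (profA$lo > 2L || profB$hi < RL - 2L) return(NULL)
  prefA <- c(rep(0L, profA$lo), cumsum(profA$match))          # matches in [loA, x)
  idxA <- function(x) ifelse(x <= profA$lo, 0L, prefA[min(x, profA$hi)])
  sufB_raw <- rev(cumsum(rev(profB$match)))                   # matches in [x, hiB)
  idxB <- function(x) {
    if (x >= profB$hi) 0L else sufB_raw[max(x, profB$lo) - profB$lo + 1L]
  }
  x_lo <- max(profB$lo, profA$lo + 1L)
  x_hi <- min(profA$hi, profB$hi - 1L)
  if (x_lo > x_hi) return(NULL)
  xs <- x_lo:x_hi
  sc <- vapply(xs, function(x) idxA(x) + idxB(x), 0L)
  x <- xs[which.max(sc)]                                      # leftmost maximum
  mismA <- (x - profA$lo) - idxA(x)
  mismB <- (profB$hi - x) - idxB(x)
  if (mismA > budget || mismB > budget) return(NULL)
  list(
    x = x, score = max(sc),
    covA = c(profA$lo, x), covB = c(x, profB$hi),
    mismA = mismA, mismB = mismB
  )
}

empty_aln_row <- function() {
  list(
    status = NA_character_, orientation = NA_character_,
    tx = NA_character_, gene = NA_character_,
    t_start = NA_integer_, t_end = NA_integer_,
    r_start = NA_integer_, r_end = NA_integer_,
    tx2 = NA_character_, gene2 = NA_character_,
    t_start2 = NA_integer_, t_end2 = NA_integer_,
    r_start2 = NA_integer_, r_end2 = NA_integer_,
    split_pos = NA_integer_
  )
}

decide_alignments <- function(cand, enc_fwd, enc_rev, index, RL, k, nk, params, n) {
  ref <- index$reference
  budget <- params$max_mismatches_per_segment
  min_clip_aligned <- max(30L, k)

  base <- empty_aln_row()
  out <- lapply(base, function(v) rep(v, n))
  out$status <- rep("unmapped", n)
  fill_row <- function(r, row) {
    for (nm in names(row)) out[[nm]][r] <<- row[[nm]]
  }

  if (nrow(cand) == 0L) {
    dt <- data.table::as.data.table(out)
    dt$read <- seq_len(n)
    return(dt)
  }

  data.table::setorder(cand, read, orient, tx, diag)

  # bulk path: reads with a perfect full-length chain
  perf <- cand[cand$N == nk, ]
  handled <- integer(0)
  if (nrow(perf) > 0L) {
    gene_of <- ref$gene_id
    ng <- perf[, list(ng = data.table::uniqueN(gene_of[tx])), by = "read"]
    amb_reads <- ng$read[ng$ng > 1L]
    out$status[amb_reads] <- "ambiguous"
    uni <- perf[!(perf$read %in% amb_reads), ]
    if (nrow(uni) > 0L) {
      first <- uni[, list(
        orient = orient[1L], tx = tx[1L], diag = diag[1L]
      ), by = "read"]
      r <- first$read
      out$status[r] <- "unique"
      out$orientation[r] <- ifelse(first$orient == 1L, "+", "-")
      out$tx[r] <- ref$transcript_id[first$tx]
      out$gene[r] <- ref$gene_id[first$tx]
      out$r_start[r] <- 0L
      out$r_end[r] <- RL
      out$t_start[r] <- first$diag
      out$t_end[r] <- first$diag + RL
      handled <- c(amb_reads, r)
    } else {
      handled <- amb_reads
    }
  }

  irregular <- setdiff(unique(cand$read), handled)
  cand_by_read <- if (length(irregular) > 0L) {
    split(cand[cand$read %in% irregular, ], by = "read")
  } else list()

  for (r in irregular) {
    row <- empty_aln_row()
    cc <- cand_by_read[[as.character(r)]]
    # imperfect: extend the strongest chains
    data.table::setorder(cc, -N, orient, tx, diag)
    cc <- head(cc, 12L)
    profs <- vector("list", nrow(cc))
    segs <- vector("list", nrow(cc))
    for (i in seq_len(nrow(cc))) {
      enc <- if (cc$orient[i] == 1L) enc_fwd else enc_rev
      profs[[i]] <- candidate_profile(enc[, r], index$tx_codes[[cc$tx[i]]], cc$diag[i])
      segs[[i]] <- extend_candidate(profs[[i]], cc$rmin[i], cc$rmax[i], k, budget)
    }
    seg_len <- vapply(segs, function(s) if (is.null(s)) 0L else s[2] - s[1], 0L)
    best <- which.max(seg_len)
    if (seg_len[best] >= RL - 2L) {
      # full-length (with mismatches); check cross-gene ties
      ties <- which(seg_len == seg_len[best])
      genes <- unique(ref$gene_id[cc$tx[ties]])
      if (length(genes) > 1L) {
        row$status <- "ambiguous"
      } else {
        s <- segs[[best]]
        row$status <- "unique"
        row$orientation <- if (cc$orient[best] == 1L) "+" else "-"
        row$tx <- ref$transcript_id[cc$tx[best]]
        row$gene <- ref$gene_id[cc$tx[best]]
        row$r_start <- s[1]; row$r_end <- s[2]
        row$t_start <- s[1] + cc$diag[best]; row$t_end <- s[2] + cc$diag[best]
      }
      fill_row(r, row)
      next
    }
    # split: a prefix candidate and a suffix candidate from different genes,
    # same read orientation, jointly explaining all but <= 2 read bases
    split_row <- NULL
    for (oi in 1:2) {
      io <- which(cc$orient == oi & !vapply(profs, is.null, TRUE))
      if (length(io) < 2L) next
      best_sp <- NULL
      best_pair <- NULL
      tie_gene_pair <- FALSE
      for (a in io) for (b in io) {
        if (a == b) next
        if (ref$gene_id[cc$tx[a]] == ref$gene_id[cc$tx[b]]) next
        sp <- split_score(profs[[a]], profs[[b]], RL, budget)
        if (is.null(sp)) next
        cov <- (sp$covA[2] - sp$covA[1]) + (sp$covB[2] - sp$covB[1])
        if (cov < RL - 2L || sp$score < RL - 2L - budget) next
        if (is.null(best_sp) || sp$score > best_sp$score) {
          best_sp <- sp; best_pair <- c(a, b); tie_gene_pair <- FALSE
        } else if (sp$score == best_sp$score &&
                   (ref$gene_id[cc$tx[a]] != ref$gene_id[cc$tx[best_pair[1]]] ||
                    ref$gene_id[cc$tx[b]] != ref$gene_id[cc$tx[best_pair[2]]])) {
          tie_gene_pair <- TRUE
        }
      }
      if (!is.null(best_sp)) {
        if (tie_gene_pair) {
          row$status <- "ambiguous"
          split_row <- row
        } else {
          a <- best_pair[1]; b <- best_pair[2]
          x <- best_sp$x
          row$status <- "split"
          row$orientation <- if (oi == 1L) "+" else "-"
          row$tx <- ref$transcript_id[cc$tx[a]]
          row$gene <- ref$gene_id[cc$tx[a]]
          row$r_start <- best_sp$covA[1]; row$r_end <- x
          row$t_start <- best_sp$covA[1] + cc$diag[a]; row$t_end <- x + cc$diag[a]
          row$tx2 <- ref$transcript_id[cc$tx[b]]
          row$gene2 <- ref$gene_id[cc$tx[b]]
          row$r_start2 <- x; row$r_end2 <- best_sp$covB[2]
          row$t_start2 <- x + cc$diag[b]; row$t_end2 <- best_sp$covB[2] + cc$diag[b]
          row$split_pos <- x
          split_row <- row
        }
        break
      }
    }
    if (!is.null(split_row)) {
      fill_row(r, split_row)
      next
    }
    if (seg_len[best] >= min_clip_aligned) {
      # soft-clipped single-segment alignment
      s <- segs[[best]]
      row$status <- "unique"
      row$orientation <- if (cc$orient[best] == 1L) "+" else "-"
      row$tx <- ref$transcript_id[cc$tx[best]]
      row$gene <- ref$gene_id[cc$tx[best]]
      row$r_start <- s[1]; row$r_end <- s[2]
      row$t_start <- s[1] + cc$diag[best]; row$t_end <- s[2] + cc$diag[best]
    } else {
      row$status <- "unmapped"
    }
    fill_row(r, row)
  }

  dt <- data.table::as.data.table(out)
  dt$read <- seq_len(n)
  dt
}

#' @export
print.spet_alignments <- function(x, ...) {
  tab <- table(x$alignments$status)
  cat("<spet_alignments> ", nrow(x$alignments), " reads: ",
      paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
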