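# Independent brute-force oracles used to validate the engine and the
# aligner.  They share only the *stated contracts* with the package code:
# the window DP here is a vectorised pure-R feasibility DP over explicit
# windows, and the local-alignment oracle is a plain R dynamic program.

ORACLE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
                 R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                 B = 14L, D = 13L, H = 11L, V = 7L, N = 15L)

oracle_encode <- function(seq) unname(ORACLE_BITS[strsplit(seq, "")[[1]]])

# all windows of length |primer| +/- g_max alignable end-to-end to the primer
# within the per-primer budgets; counts are the minimal-total (then
# minimal-gap) feasible pair
oracle_windows <- function(target, primer, n_max, g_max) {
  tb <- oracle_encode(toupper(target))
  pb <- oracle_encode(toupper(primer))
  N <- length(tb); L <- length(pb)
  gw <- g_max + 1L
  width <- (n_max + 1L) * gw
  FULL <- bitwShiftL(1L, width) - 1L
  keepg <- 0L
  for (b in 0:(width - 1L))
    if (b %% gw < g_max) keepg <- bitwOr(keepg, bitwShiftL(1L, b))
  res <- list()
  for (W in max(1L, L - g_max):(L + g_max)) {
    nst <- N - W + 1L
    if (nst < 1L) next
    TM <- matrix(tb[outer(seq_len(W), 0:(nst - 1L), `+`)], nrow = W)
    prev <- lapply(0:W, function(j)
      rep(if (j <= g_max) bitwShiftL(1L, j) else 0L, nst))
    for (i in seq_len(L)) {
      cur <- vector("list", W + 1L)
      cur[[1L]] <- bitwShiftL(bitwAnd(prev[[1L]], keepg), 1L)
      pbit <- pb[i]
      for (j in seq_len(W)) {
        tj <- TM[j, ]
        ok <- tj != 15L & bitwAnd(tj, bitwNot(pbit)) == 0L
        diag <- prev[[j]]
        m <- ifelse(ok, diag, bitwAnd(bitwShiftL(diag, gw), FULL))
        up <- bitwShiftL(bitwAnd(prev[[j + 1L]], keepg), 1L)
        left <- bitwShiftL(bitwAnd(cur[[j]], keepg), 1L)
        cur[[j + 1L]] <- bitwOr(bitwOr(m, up), left)
      }
      prev <- cur
    }
    fin <- prev[[W + 1L]]
    hit <- which(fin != 0L)
    if (!length(hit)) next
    mm <- integer(length(hit)); gg <- integer(length(hit))
    found <- logical(length(hit))
    for (tot in 0:(n_max + g_max)) {
      for (g in 0:min(tot, g_max)) {
        m_ <- tot - g
        if (m_ > n_max) next
        bit <- bitwShiftL(1L, m_ * gw + g)
        sel <- !found & bitwAnd(fin[hit], bit) != 0L
        mm[sel] <- m_; gg[sel] <- g; found[sel] <- TRUE
      }
    }
    res[[length(res) + 1L]] <- data.frame(
      start = hit, end = hit + W - 1L, mismatches = mm, gaps = gg)
  }
  if (length(res)) do.call(rbind, res)
  else data.frame(start = integer(0), end = integer(0),
                  mismatches = integer(0), gaps = integer(0))
}

# stated reduction rule, implemented as repeated best-pick-and-discard
oracle_reduce <- function(raw, primer_len) {
  sel <- raw[0, , drop = FALSE]
  cand <- raw
  while (nrow(cand)) {
    o <- order(cand$mismatches + cand$gaps, cand$gaps,
               abs(cand$end - cand$start + 1L - primer_len),
               cand$start, cand$end)
    best <- cand[o[1], , drop = FALSE]
    sel <- rbind(sel, best)
    cand <- cand[cand$end < best$start | cand$start > best$end, ,
                 drop = FALSE]
  }
  sel[order(sel$start, sel$end), , drop = FALSE]
}

oracle_sites <- function(target, primer, params, strand) {
  oriented <- if (strand == "+") primer else oracle_revcomp(primer)
  oracle_reduce(oracle_windows(target, oriented, params$n_max, params$g_max),
                nchar(primer))
}

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", U = "A",
                 R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                 B = "V", D = "H", H = "D", V = "B", N = "N")

oracle_revcomp <- function(seq)
  paste(rev(unname(ORACLE_COMP[strsplit(toupper(seq), "")[[1]]])),
        collapse = "")

# full brute-force in silico PCR: sites by window DP, pairing by filtered
# cross product in both orientations, then the combined-edit cap
oracle_simulate <- function(target, fw, rv, params) {
  target <- toupper(target)
  f_plus <- oracle_sites(target, fw, params, "+")
  f_minus <- oracle_sites(target, fw, params, "-")
  r_plus <- oracle_sites(target, rv, params, "+")
  r_minus <- oracle_sites(target, rv, params, "-")
  combine <- function(left, right, strand, fw_is_left) {
    if (!nrow(left) || !nrow(right)) return(NULL)
    g <- expand.grid(l = seq_len(nrow(left)), r = seq_len(nrow(right)))
    span <- right$end[g$r] - left$start[g$l] + 1L
    ok <- left$end[g$l] < right$start[g$r] &
      span >= params$d_min & span <= params$d_max
    g <- g[ok, , drop = FALSE]
    if (!nrow(g)) return(NULL)
    fw_i <- if (fw_is_left) g$l else g$r
    rv_i <- if (fw_is_left) g$r else g$l
    fw_h <- if (fw_is_left) left else right
    rv_h <- if (fw_is_left) right else left
    data.frame(strand = strand,
               start = left$start[g$l], end = right$end[g$r],
               product_length = span[ok],
               fw_mismatches = fw_h$mismatches[fw_i],
               fw_gaps = fw_h$gaps[fw_i],
               rv_mismatches = rv_h$mismatches[rv_i],
               rv_gaps = rv_h$gaps[rv_i],
               stringsAsFactors = FALSE)
  }
  out <- rbind(combine(f_plus, r_minus, "+", TRUE),
               combine(r_plus, f_minus, "-", FALSE))
  if (is.null(out) || !nrow(out))
    return(data.frame(strand = character(0), start = integer(0),
                      end = integer(0), product_length = integer(0),
                      fw_mismatches = integer(0), fw_gaps = integer(0),
                      rv_mismatches = integer(0), rv_gaps = integer(0),
                      stringsAsFactors = FALSE))
  total <- out$fw_mismatches + out$fw_gaps + out$rv_mismatches + out$rv_gaps
  out <- out[total <= params$total_edit_max, , drop = FALSE]
  out <- out[!duplicated(out[, c("strand", "start", "end")]), , drop = FALSE]
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exhaustive local alignment with the same lexicographic objective
# (max score, min gap columns, min mismatches, min gap opens); returns the
# optimal counts, which the objective makes unique
oracle_local_align <- function(a, b, scoring = amplimine::probe_scoring()) {
  av <- oracle_encode(toupper(a)); bv <- oracle_encode(toupper(b))
  la <- length(av); lb <- length(bv)
  ma <- scoring$match; mi <- scoring$mismatch
  go <- scoring$gap_open; ge <- scoring$gap_extend
  NEG <- -1e9
  # state vectors: score, gapcols, mismatches, opens, identities
  bad <- c(NEG, 0, 0, 0, 0)
  zero <- c(0, 0, 0, 0, 0)
  better <- function(x, y) {
    if (x[1] != y[1]) return(x[1] > y[1])
    if (x[2] != y[2]) return(x[2] < y[2])
    if (x[3] != y[3]) return(x[3] < y[3])
    x[4] < y[4]
  }
  M <- Ix <- Iy <- array(rep(bad, (la + 1) * (lb + 1)),
                         dim = c(5, la + 1, lb + 1))
  best <- bad
  for (i in 1:la) {
    for (j in 1:lb) {
      ok <- bv[j] != 15L && bitwAnd(bv[j], bitwNot(av[i])) == 0L
      d <- zero
      for (cand in list(M[, i, j], Ix[, i, j], Iy[, i, j]))
        if (cand[1] > NEG && better(cand, d)) d <- cand
      m <- d + c(if (ok) ma else mi, 0, if (ok) 0 else 1, 0, if (ok) 1 else 0)
      M[, i + 1, j + 1] <- m
      x <- bad
      for (cand in list(M[, i, j + 1] + c(go + ge, 1, 0, 1, 0),
                        Iy[, i, j + 1] + c(go + ge, 1, 0, 1, 0),
                        Ix[, i, j + 1] + c(ge, 1, 0, 0, 0)))
        if (cand[1] > NEG + 1e6 && (x[1] <= NEG || better(cand, x))) x <- cand
      Ix[, i + 1, j + 1] <- x
      y <- bad
      for (cand in list(M[, i + 1, j] + c(go + ge, 1, 0, 1, 0),
                        Ix[, i + 1, j] + c(go + ge, 1, 0, 1, 0),
                        Iy[, i + 1, j] + c(ge, 1, 0, 0, 0)))
        if (cand[1] > NEG + 1e6 && (y[1] <= NEG || better(cand, y))) y <- cand
      Iy[, i + 1, j + 1] <- y
      if (m[1] > 0 && better(m, best)) best <- m
    }
  }
  if (best[1] <= 0) return(NULL)
  list(score = best[1], gaps = best[2], mismatches = best[3],
       opens = best[4], identities = best[5])
}

random_seq <- function(n, letters = c("A", "C", "G", "T"))
  paste(sample(letters, n, replace = TRUE), collapse = "")
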