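## Independent brute-force oracle: plain-string enumeration of end events,
## Alu membership, motif families and CGCG cleavage registers. Shares only
## the documented conventions with the implementation, none of its code.
fragmaOracle <- function(refStr, frags0, alu0) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  inAlu <- function(p) any(vapply(alu0, function(iv) p >= iv[1] && p < iv[2],
                                  logical(1)))
  ev <- data.frame(pos = integer(), strand = character(),
                   motif = character(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(frags0))) {
    s0 <- frags0$start[i]; e0 <- frags0$end[i]
    ml <- substr(refStr, s0 + 1, s0 + 3)
    mr <- rc(substr(refStr, e0 - 2, e0))
    if (inAlu(s0) && grepl("^[ACGT]{3}$", ml))
      ev <- rbind(ev, data.frame(pos = s0, strand = "+", motif = ml))
    if (inAlu(e0 - 1) && grepl("^[ACGT]{3}$", mr))
      ev <- rbind(ev, data.frame(pos = e0 - 1, strand = "-", motif = mr))
  }
  CGN <- c("CGA", "CGC", "CGG", "CGT"); NCG <- c("ACG", "CCG", "GCG", "TCG")
  tot <- nrow(ev)
  r <- vapply(c(CGN, NCG), function(m) sum(ev$motif == m) / max(tot, 1),
              numeric(1))
  names(r) <- paste0("r_", c(CGN, NCG))
  nCGN <- sum(ev$motif %in% CGN); nNCG <- sum(ev$motif %in% NCG)
  r <- c(r, r_CGN_over_NCG = nCGN / max(nNCG, 1))
  ## CGCG registers: every occurrence fully inside an Alu interval
  occ <- integer(0)
  for (p0 in 0:(nchar(refStr) - 4)) {
    if (substr(refStr, p0 + 1, p0 + 4) == "CGCG" &&
        any(vapply(alu0, function(iv) p0 >= iv[1] && p0 + 4 <= iv[2],
                   logical(1))))
      occ <- c(occ, p0)
  }
  reg <- list()  # key "pos:strand" -> class label, precedence CGC>GCG>NCG>CGN
  addReg <- function(p, st, cls, prio) {
    k <- paste0(p, ":", st)
    if (is.null(reg[[k]]) || reg[[k]]$prio > prio)
      reg[[k]] <<- list(cls = cls, prio = prio)
  }
  base <- function(p) if (p < 0 || p >= nchar(refStr)) NA
                      else substr(refStr, p + 1, p + 1)
  for (p0 in occ) {
    addReg(p0, "+", "c_CGC", 1); addReg(p0 + 1, "+", "c_GCG", 2)
    addReg(p0 + 3, "-", "c_CGC", 1); addReg(p0 + 2, "-", "c_GCG", 2)
    bL <- base(p0 - 1); bR <- base(p0 + 4)
    if (!is.na(bL) && bL %in% names(comp)[1:4]) {
      addReg(p0 - 1, "+", paste0("c_NCG_", bL), 3)
      addReg(p0 + 1, "-", paste0("c_CGN_", comp[[bL]]), 4)
    }
    if (!is.na(bR) && bR %in% names(comp)[1:4]) {
      addReg(p0 + 2, "+", paste0("c_CGN_", bR), 4)
      addReg(p0 + 4, "-", paste0("c_NCG_", comp[[bR]]), 3)
    }
  }
  nm <- c(paste0("c_NCG_", c("A", "C", "G", "T")), "c_CGC", "c_GCG",
          paste0("c_CGN_", c("A", "C", "G", "T")))
  cnt <- setNames(numeric(10), nm)
  for (i in seq_len(nrow(ev))) {
    k <- paste0(ev$pos[i], ":", ev$strand[i])
    if (!is.null(reg[[k]])) cnt[reg[[k]]$cls] <- cnt[reg[[k]]$cls] + 1
  }
  totC <- sum(cnt)
  cr <- if (totC > 0) cnt / totC else cnt
  ncgC <- sum(cnt[1:4]); cgcC <- cnt[["c_CGC"]]; cgnC <- sum(cnt[7:10])
  c(r, cr, c_CGC_over_NCG = cgcC / max(ncgC, 1),
    c_CGN_over_CGC = cgnC / max(cgcC, 1))
}

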