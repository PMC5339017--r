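# Independent brute-force folding oracle: enumerates every nested secondary
# structure of a short sequence (minimum hairpin 3, canonical + wobble pairs)
# and evaluates each with a stand-alone R implementation of the engine's
# energy model. Used to validate the dynamic programming (MFE) and the
# partition function (pair probabilities) on small instances. The constants
# are frozen copies; the decomposition logic is written independently of the
# C++ recursions.

.ORACLE_PAIR_IDX <- c(CG = 1, GC = 2, GU = 3, UG = 4, AU = 5, UA = 6)

.ORACLE_STACK <- matrix(c(
  -240, -330, -210, -140, -210, -210,
  -330, -340, -250, -150, -220, -240,
  -210, -250,  130,  -50, -140, -130,
  -140, -150,  -50,   30,  -60, -100,
  -210, -220, -140,  -60, -110,  -90,
  -210, -240, -130, -100,  -90, -130), 6, 6, byrow = TRUE)

oracle_ptype <- function(x, y) {
  v <- .ORACLE_PAIR_IDX[paste0(x, y)]
  if (is.na(v)) -1L else as.integer(v)
}

oracle_hairpin <- function(n) {
  h <- c(540, 560, 570, 540, 600, 550, 640)
  if (n < 3) return(Inf)
  if (n <= 9) return(h[n - 2])
  round(640 + 107.856 * log(n / 9))
}

oracle_bulge <- function(n) {
  b <- c(380, 280, 320, 360, 400, 440)
  if (n <= 6) return(b[n])
  round(440 + 107.856 * log(n / 6))
}

oracle_internal <- function(n) {
  if (n == 2) return(150)
  if (n == 3) return(220)
  il <- c(110, 200, 200)
  if (n <= 6) return(il[n - 3])
  round(200 + 107.856 * log(n / 6))
}

# energy (kcal/mol) of one structure given as a 1-based pair table
oracle_energy <- function(seq, pt) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  au <- function(i, j) if (oracle_ptype(ch[i], ch[j]) >= 3) 50 else 0
  e <- 0
  opens <- which(pt > seq_len(n))
  for (i in opens) {
    j <- pt[i]
    kids <- list()
    k <- i + 1
    while (k < j) {
      if (pt[k] > k) { kids[[length(kids) + 1]] <- c(k, pt[k]); k <- pt[k] + 1 }
      else k <- k + 1
    }
    if (length(kids) == 0) {
      e <- e + oracle_hairpin(j - i - 1) + au(i, j)
    } else if (length(kids) == 1) {
      k <- kids[[1]][1]; l <- kids[[1]][2]
      u1 <- k - i - 1; u2 <- j - l - 1
      st <- .ORACLE_STACK[oracle_ptype(ch[i], ch[j]), oracle_ptype(ch[l], ch[k])]
      if (u1 == 0 && u2 == 0) {
        e <- e + st
      } else if (u1 == 0 || u2 == 0) {
        u <- u1 + u2
        e <- e + oracle_bulge(u) +
          if (u == 1) st else au(i, j) + au(k, l)
      } else {
        e <- e + oracle_internal(u1 + u2) + min(300, 60 * abs(u1 - u2)) +
          au(i, j) + au(k, l)
      }
    } else {
      e <- e + 340 + 40 + au(i, j) +
        sum(vapply(kids, function(kd) 40 + au(kd[1], kd[2]), numeric(1)))
    }
  }
  k <- 1
  while (k <= n) {               # external-loop helix-end penalties
    if (pt[k] > k) { e <- e + au(k, pt[k]); k <- pt[k] + 1 } else k <- k + 1
  }
  e / 100
}

# all nested structures (as pair tables) of a short sequence
oracle_enumerate <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  memo <- new.env(parent = emptyenv())
  gen <- function(i, j) {
    if (j - i < 4) return(list(integer(0)))
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    res <- gen(i + 1, j)
    for (k in (i + 4):j) {
      if (oracle_ptype(ch[i], ch[k]) > 0) {
        for (a in gen(i + 1, k - 1)) for (b in gen(k + 1, j)) {
          res[[length(res) + 1]] <- c(i, k, a, b)
        }
      }
    }
    memo[[key]] <- res
    res
  }
  lapply(gen(1, n), function(v) {
    pt <- integer(n)
    if (length(v)) {
      m <- matrix(v, ncol = 2, byrow = TRUE)
      pt[m[, 1]] <- m[, 2]
      pt[m[, 2]] <- m[, 1]
    }
    pt
  })
}

oracle_mfe <- function(seq) {
  structs <- oracle_enumerate(seq)
  min(0, min(vapply(structs, function(pt) oracle_energy(seq, pt), numeric(1))))
}

oracle_pair_probs <- function(seq) {
  structs <- oracle_enumerate(seq)
  es <- vapply(structs, function(pt) oracle_energy(seq, pt), numeric(1))
  w <- exp(-es / 0.61633)
  n <- nchar(seq)
  P <- matrix(0, n, n)
  for (s in seq_along(structs)) {
    pt <- structs[[s]]
    idx <- which(pt > seq_len(n))
    for (i in idx) P[i, pt[i]] <- P[i, pt[i]] + w[s]
  }
  P <- P / sum(w)
  P + t(P)
}
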