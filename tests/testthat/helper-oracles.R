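# Independent brute-force oracles used to validate the package's
# implementations. These deliberately share no code with the package.

# flood-fill connected-component count/labels (queue-based, plain R)
oracle_label <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  nxt <- 0L
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j] == 0 || lab[i, j] != 0) next
    nxt <- nxt + 1L
    queue <- matrix(c(i, j), 1, 2)
    lab[i, j] <- nxt
    while (nrow(queue) > 0) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(nb))) {
        ii <- p[1] + nb[k, 1]; jj <- p[2] + nb[k, 2]
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W &&
            mask[ii, jj] != 0 && lab[ii, jj] == 0) {
          lab[ii, jj] <- nxt
          queue <- rbind(queue, c(ii, jj))
        }
      }
    }
  }
  lab
}

# literal k x k all-ones dilation, anchor floor(k/2): shift-OR over offsets
oracle_dilate <- function(mask, k = 16) {
  H <- nrow(mask); W <- ncol(mask)
  a <- k %/% 2
  out <- matrix(0L, H, W)
  for (du in (-a):(k - 1 - a)) for (dv in (-a):(k - 1 - a)) {
    sr <- max(1, 1 + du):min(H, H + du)
    dr <- sr - du
    sc <- max(1, 1 + dv):min(W, W + dv)
    dc <- sc - dv
    out[dr, dc] <- out[dr, dc] | mask[sr, sc]
  }
  out * 1L
}

# literal cluster rule: dilate, label domains, count components per domain
oracle_clusters <- function(mask, k = 16, min_members = 5) {
  dil <- oracle_dilate(mask, k)
  dlab <- oracle_label(dil, 8)
  clab <- oracle_label(mask, 8)
  ncomp <- max(clab)
  if (ncomp == 0)
    return(list(clu_num = 0L, clu_max_num = 0L, members = list()))
  dom <- vapply(seq_len(ncomp), function(l) {
    px <- which(clab == l, arr.ind = TRUE)[1, , drop = FALSE]
    dlab[px]
  }, integer(1))
  members <- list()
  for (d in unique(dom)) {
    mem <- which(dom == d)
    if (length(mem) > min_members) members[[length(members) + 1L]] <- mem
  }
  list(clu_num = length(members),
       clu_max_num = if (length(members))
         max(lengths(members)) else 0L,
       members = members)
}

# exact (symmetric) Hausdorff distance between two point sets (n x 2)
oracle_hausdorff <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(Inf)
  d <- function(p, q) {
    max(apply(p, 1, function(x)
      min(sqrt((q[, 1] - x[1])^2 + (q[, 2] - x[2])^2))))
  }
  max(d(a, b), d(b, a))
}

# per-pixel loop confusion counts
oracle_confusion <- function(pred, gt) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    if (pred[i, j] == 1 && gt[i, j] == 1) tp <- tp + 1L
    else if (pred[i, j] == 0 && gt[i, j] == 0) tn <- tn + 1L
    else if (pred[i, j] == 1) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

# Mann-Whitney AUC: fraction of (pos, neg) pairs ranked correctly,
# ties counted one half
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# small random lesion mask for oracle comparisons
random_lesion_mask <- function(size = 96, n_lesions = 12, seed = 1) {
  set.seed(seed)
  m <- matrix(0L, size, size)
  for (i in seq_len(n_lesions)) {
    r <- sample.int(size - 6, 1) + 3
    c <- sample.int(size - 6, 1) + 3
    rad <- sample(0:2, 1)
    m[max(1, r - rad):min(size, r + rad),
      max(1, c - rad):min(size, c + rad)] <- 1L
  }
  m
}

# tiny phantom spec for fast property tests
tiny_spec <- function(label = "benign", n_micro = 6, n_macro = 2,
                      n_clusters = 0) {
  phantom_spec(image_size = 128, n_micro = n_micro, n_macro = n_macro,
               macro_diameter_px = c(7, 12), n_clusters = n_clusters,
               cluster_members = c(6, 8), cluster_radius_px = 18,
               label = label)
}
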