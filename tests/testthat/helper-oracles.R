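# Independent brute-force oracles and shared fixtures.

# Connected-component labelling by breadth-first search (independent of
# the package's union-find implementation).
bfs_label <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nbr <- if (connectivity == 4L)
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else
    cbind(rep(-1:1, each = 3), rep(-1:1, 3))[-5, , drop = FALSE]
  nxt <- 0L
  for (start in which(mask == 1 & lab == 0L)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      r <- (q - 1L) %% H + 1L; cc <- (q - 1L) %/% H + 1L
      for (k in seq_len(nrow(nbr))) {
        rr <- r + nbr[k, 1]; c2 <- cc + nbr[k, 2]
        if (rr >= 1 && rr <= H && c2 >= 1 && c2 <= W &&
            mask[rr, c2] == 1 && lab[rr, c2] == 0L) {
          lab[rr, c2] <- nxt
          queue <- c(queue, (c2 - 1L) * H + rr)
        }
      }
    }
  }
  lab
}

# Oracle for the flood-fill mask update: keep every ink component that
# intersects the seed.
oracle_update <- function(ink, seed, connectivity = 8L) {
  lab <- bfs_label(ink, connectivity)
  keep <- setdiff(unique(lab[seed == 1]), 0L)
  (matrix(lab %in% keep, nrow(ink), ncol(ink))) * 1
}

# O(n^2) pairwise bbox intersection test (0-based half-open boxes).
any_boxes_overlap <- function(boxes) {
  n <- length(boxes)
  if (n < 2) return(FALSE)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- boxes[[i]]; b <- boxes[[j]]
    if (a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4]) return(TRUE)
  }
  FALSE
}

# Independent greedy IoU matcher over explicit pair enumeration.
oracle_match_count <- function(pred, truth, thr) {
  pairs <- list()
  for (i in seq_along(pred)) for (j in seq_along(truth)) {
    a <- pred[[i]]; b <- truth[[j]]
    ih <- min(a[3], b[3]) - max(a[1], b[1])
    iw <- min(a[4], b[4]) - max(a[2], b[2])
    iou <- if (ih > 0 && iw > 0) {
      inter <- ih * iw
      inter / ((a[3] - a[1]) * (a[4] - a[2]) +
               (b[3] - b[1]) * (b[4] - b[2]) - inter)
    } else 0
    pairs[[length(pairs) + 1L]] <- c(i, j, iou)
  }
  if (!length(pairs)) return(0L)
  pm <- do.call(rbind, pairs)
  pm <- pm[order(-pm[, 3]), , drop = FALSE]
  up <- logical(length(pred)); ut <- logical(length(truth)); m <- 0L
  for (k in seq_len(nrow(pm))) {
    if (pm[k, 3] < thr) break
    i <- pm[k, 1]; j <- pm[k, 2]
    if (!up[i] && !ut[j]) { up[i] <- TRUE; ut[j] <- TRUE; m <- m + 1L }
  }
  m
}

# Heavy-atom count straight from the SMILES text: every uppercase
# element symbol or bracket atom, minus explicit hydrogens. Independent
# of OpenBabel. Valid for the organic-subset SMILES in the fixtures.
regex_heavy_count <- function(smiles) {
  s <- smiles
  s <- gsub("\\[[-A-Za-z@+0-9]*\\]", "X", s)  # bracket atom -> one
  s <- gsub("Cl|Br", "X", s)
  sum(strsplit(s, "")[[1]] %in% c("X", "B", "C", "N", "O", "P", "S", "F", "I",
                                  "b", "c", "n", "o", "p", "s"))
}

# Shared fixtures, built once per test run.
fixture_env <- new.env(parent = emptyenv())

fixture_library <- function() {
  if (is.null(fixture_env$lib)) fixture_env$lib <- molecule_library()
  fixture_env$lib
}

fixture_pages <- function(n, seed, key = paste0("p", n, "_", seed), ...) {
  if (is.null(fixture_env[[key]])) {
    cfg <- synthesis_config(n_pages = n, seed = seed, ...)
    lib <- fixture_library()
    fixture_env[[key]] <- local({
      set.seed(seed)
      lapply(seq_len(n), function(i) generate_page_pair(lib, cfg))
    })
  }
  fixture_env[[key]]
}

synth_negative_fixture <- function() {
  set.seed(123)
  synth_negative("blob")
}

tiny_cfg <- function() encoder_config(image_size = 16L, patch_size = 8L,
                                      embed_dim = 8L, n_blocks = 1L,
                                      n_heads = 2L, adapter_dim = 4L,
                                      neck_dim = 8L, dec_dim1 = 4L,
                                      dec_dim2 = 4L)
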