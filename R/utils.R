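# internal helpers shared across modules

# condition constructor: all package errors carry a subclass so callers can
# distinguish validation failures programmatically
cc_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "conncog_error"),
                      call = call))
}

cc_warn <- function(msg) warning(msg, call. = FALSE)

#' Number of unordered node pairs
#'
#' Count of potential undirected edges (excluding self-loops) among
#' `n_nodes` regions; 76 nodes give 2850 pairs.
#'
#' @param n_nodes number of network nodes.
#' @return integer count `n_nodes * (n_nodes - 1) / 2`.
#' @export
#' @examples
#' n_node_pairs(76)
n_node_pairs <- function(n_nodes) {
  stopifnot(is.numeric(n_nodes), n_nodes >= 0)
  as.integer(n_nodes * (n_nodes - 1) / 2)
}

# largest-remainder apportionment of `total` draws across strata with the
# given counts; returns integer allocation summing exactly to total
largest_remainder <- function(counts, total) {
  if (total > sum(counts)) {
    cc_stop("cannot allocate more draws than available subjects",
            "conncog_allocation_error")
  }
  quota <- counts / sum(counts) * total
  alloc <- floor(quota)
  short <- total - sum(alloc)
  if (short > 0) {
    take <- order(quota - alloc, decreasing = TRUE)[seq_len(short)]
    alloc[take] <- alloc[take] + 1
  }
  # never allocate beyond a stratum's size
  over <- which(alloc > counts)
  while (length(over)) {
    excess <- sum(alloc[over] - counts[over])
    alloc[over] <- counts[over]
    room <- which(alloc < counts)
    give <- room[order(quota[room] - alloc[room], decreasing = TRUE)]
    for (i in give) {
      if (excess == 0) break
      alloc[i] <- alloc[i] + 1
      excess <- excess - 1
    }
    over <- which(alloc > counts)
  }
  as.integer(alloc)
}

# "42 (55.3%)" style count with one-decimal percentage
format_count_pct <- function(count, total) {
  sprintf("%d (%.1f%%)", count, round(100 * count / total, 1))
}

# FNV-1a 32-bit hash of a character scalar; used to stamp config identity
# into output headers without a digest dependency
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x)) %% 256
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# seeded sub-stream: derive a reproducible child seed below 2^31
derive_seed <- function(seed, salt) {
  (seed * 48271 + salt) %% 2147483647
}
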