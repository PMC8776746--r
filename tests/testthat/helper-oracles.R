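# Exhaustive betweenness oracle: enumerate all shortest paths per pair by
# backtracking over BFS levels and count interior traversals.
brute_betweenness <- function(g) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  btw <- setNames(rep(0, n), igraph::V(g)$name)
  D <- igraph::distances(g)
  count_paths <- function(s, t) {
    # returns list(total, through = counts per vertex)
    through <- rep(0, n)
    total <- 0
    walk <- function(v, path) {
      if (v == s) {
        total <<- total + 1
        inner <- setdiff(path, c(s, t))
        through[inner] <<- through[inner] + 1
        return(invisible())
      }
      for (u in which(A[, v] == 1)) {
        if (is.finite(D[s, u]) && D[s, u] == D[s, v] - 1) walk(u, c(path, u))
      }
    }
    walk(t, t)
    list(total = total, through = through)
  }
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t]) || D[s, t] < 2) next
    cp <- count_paths(s, t)
    btw <- btw + cp$through / cp$total
  }
  btw
}
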