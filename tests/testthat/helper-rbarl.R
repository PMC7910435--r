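# shared fixture builders; everything is generated in code at test time

tiny_timeline <- function(taus = c(10, 20, 30), likes = NULL, id = "u") {
  if (is.null(likes)) likes <- rep(0, length(taus) + 1)
  post_timeline(id, cumsum(c(0, taus)), likes)
}

# four well-separated log-normal blobs in (alpha, P, C) space
blob_table <- function(n_per = 50, sd = 0.15, seed = 7) {
  set.seed(seed)
  blob <- function(mu) exp(matrix(rnorm(n_per * 3, rep(mu, each = n_per), sd),
                                  ncol = 3))
  out <- as.data.frame(rbind(blob(c(0, 0, 0)), blob(c(2.5, 0, 0)),
                             blob(c(0, 2.5, 0)), blob(c(0, 0, 2.5))))
  names(out) <- c("alpha", "P", "C")
  attr(out, "truth") <- rep(1:4, each = n_per)
  out
}

quiet <- function(expr) suppressWarnings(expr)
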