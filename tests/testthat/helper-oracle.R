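# Independent brute-force oracle for the over-representation tail:
# exact binomial-coefficient sums (choose() is exact for the small counts
# used here), no log-space computation shared with the implementation.
oracle_tail <- function(a, b, c, d) {
  n <- a + b + c + d
  D <- a + b
  K <- a + c
  ks <- a:min(D, K)
  sum(choose(D, ks) * choose(n - D, K - ks)) / choose(n, K)
}

oracle_point <- function(a, b, c, d) {
  n <- a + b + c + d
  choose(a + b, a) * choose(c + d, c) / choose(n, a + c)
}

pick <- function(x) x[sample.int(length(x), 1)]  # safe for length-1 ranges

random_table <- function(max_n = 40) {
  n <- pick(2:max_n)
  K <- pick(0:n)
  D <- pick(0:n)
  a <- pick(max(0, K + D - n):min(K, D))
  c(a = a, b = D - a, c = K - a, d = n - D - K + a)
}
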