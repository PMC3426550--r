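## exhaustive enumeration oracle: probability that a uniformly drawn n-subset
## of an N-gene universe (first K genes annotated) contains >= k annotated
enum_upper_tail <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)
  mean(hits >= k)
}
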