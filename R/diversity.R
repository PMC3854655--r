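## Nonparametric species richness and diversity estimators computed from an
## OTU partition. All three estimators are functions of the OTU size
## histogram alone (profile sufficiency), so each has methods both for the
## raw assignment and for its OTUSizeProfile.

#' Build the OTU size profile of an assignment
#'
#' Histogram of OTU sizes: \code{n_i} is the number of OTUs containing
#' exactly \code{i} sequences. The profile is a sufficient statistic for
#' Chao1, Shannon and ACE.
#'
#' @param x an [OTUAssignment-class], or a numeric vector of OTU sizes.
#' @return an [OTUSizeProfile-class].
#' @examples
#' sizeProfile(c(1, 1, 2, 3, 12))
#' @export
setGeneric("sizeProfile", function(x) standardGeneric("sizeProfile"))

#' @rdname sizeProfile
#' @export
setMethod("sizeProfile", "OTUAssignment", function(x) {
  sizeProfile(as.integer(table(x@labels)))
})

#' @rdname sizeProfile
#' @export
setMethod("sizeProfile", "numeric", function(x) {
  x <- as.integer(x)
  if (length(x) == 0L || any(x < 1L)) stop("OTU sizes must be positive")
  counts <- table(x)
  new("OTUSizeProfile",
      sizeCounts = structure(as.integer(counts), names = names(counts)),
      SObs = length(x), N = sum(x))
})

.ni <- function(profile, i) {
  key <- as.character(i)
  ifelse(key %in% names(profile@sizeCounts),
         profile@sizeCounts[key], 0L)
}

#' Chao1 richness estimate
#'
#' \deqn{S_{chao1} = S_{obs} + \frac{n_1 (n_1 - 1)}{2 (n_2 + 1)}}
#' the bias-corrected form, finite even with no doubletons; always at
#' least \eqn{S_{obs}}, with equality iff \eqn{n_1 \le 1}.
#'
#' @param x an [OTUAssignment-class] or [OTUSizeProfile-class].
#' @return the estimate, a single number.
#' @examples
#' chao1(sizeProfile(c(rep(1, 4), rep(2, 2), rep(5, 4))))  # 12
#' @export
setGeneric("chao1", function(x) standardGeneric("chao1"))

#' @rdname chao1
#' @export
setMethod("chao1", "OTUSizeProfile", function(x) {
  n1 <- as.double(.ni(x, 1L))
  n2 <- as.double(.ni(x, 2L))
  x@SObs + n1 * (n1 - 1) / (2 * (n2 + 1))
})

#' @rdname chao1
#' @export
setMethod("chao1", "OTUAssignment", function(x) chao1(sizeProfile(x)))

#' Shannon diversity index
#'
#' \deqn{H' = -\sum_{i=1}^{S_{obs}} \frac{n_i}{N} \ln \frac{n_i}{N}}
#' summed over OTUs with \eqn{n_i} the size of OTU i; reported in nats
#' (natural log) by default. Bounded by \eqn{0 \le H' \le \ln S_{obs}},
#' the maximum attained by equal-size OTUs.
#'
#' @param x an [OTUAssignment-class] or [OTUSizeProfile-class].
#' @param base logarithm base (default \code{exp(1)}: nats).
#' @return the index, a single number.
#' @examples
#' shannon(sizeProfile(c(5, 5)))  # log(2)
#' @export
setGeneric("shannon", function(x, base = exp(1)) standardGeneric("shannon"))

#' @rdname shannon
#' @export
setMethod("shannon", "OTUSizeProfile", function(x, base = exp(1)) {
  sizes <- as.double(names(x@sizeCounts))
  counts <- as.double(x@sizeCounts)
  prop <- sizes / x@N
  -sum(counts * prop * log(prop, base = base))
})

#' @rdname shannon
#' @export
setMethod("shannon", "OTUAssignment",
          function(x, base = exp(1)) shannon(sizeProfile(x), base = base))

#' Abundance-based coverage estimator (ACE)
#'
#' Splits OTUs at the \code{abund} threshold into rare (size at most
#' \code{abund}) and abundant, then corrects the rare-side richness by the
#' estimated sample coverage of the rare fraction:
#' \deqn{N_{rare} = \sum_{i=1}^{abund} i\, n_i, \qquad
#'       C_{ACE} = 1 - n_1 / N_{rare}}
#' \deqn{\gamma^2_{ACE} = \max\!\left(
#'       \frac{S_{rare}}{C_{ACE}}
#'       \frac{\sum_{i=1}^{abund} i (i-1) n_i}{N_{rare} (N_{rare}-1)}
#'       - 1,\; 0\right)}
#' \deqn{S_{ACE} = S_{abund} + \frac{S_{rare}}{C_{ACE}}
#'       + \frac{n_1}{C_{ACE}} \gamma^2_{ACE}}
#' With no rare OTUs the estimate is simply \eqn{S_{abund}}; when every
#' rare OTU is a singleton the coverage is zero and the estimator is
#' undefined (an error). \eqn{N_{rare} \le 1} gives \eqn{\gamma^2 = 0} (no
#' variance estimable from at most one rare individual).
#'
#' @param x an [OTUAssignment-class] or [OTUSizeProfile-class].
#' @param abund rare/abundant threshold on OTU size (default 10).
#' @return an [AceComponents-class] holding the estimate \code{SAce} and
#'   every intermediate quantity. Use [aceEstimate()] for the number alone.
#' @examples
#' ace(sizeProfile(c(1, 1, 2, 3, 12)))
#' @export
setGeneric("ace", function(x, abund = 10L) standardGeneric("ace"))

#' @rdname ace
#' @export
setMethod("ace", "OTUSizeProfile", function(x, abund = 10L) {
  abund <- as.integer(abund)
  if (abund < 1L) stop("abund must be >= 1")
  sizes <- as.integer(names(x@sizeCounts))
  counts <- as.double(x@sizeCounts)
  rare <- sizes <= abund
  SRare <- as.integer(sum(counts[rare]))
  SAbund <- x@SObs - SRare
  NRare <- as.integer(sum(sizes[rare] * counts[rare]))
  n1 <- as.double(.ni(x, 1L))
  if (NRare == 0L)
    return(new("AceComponents", abund = abund, SRare = 0L,
               SAbund = SAbund, NRare = 0L, CAce = NA_real_,
               gammaSq = 0, SAce = as.double(SAbund)))
  CAce <- 1 - n1 / NRare
  if (CAce == 0)
    stop("ACE undefined: coverage zero (all rare OTUs are singletons)")
  gammaSq <- if (NRare <= 1L) 0 else max(
    (SRare / CAce) *
      sum(sizes[rare] * (sizes[rare] - 1) * counts[rare]) /
      (as.double(NRare) * (NRare - 1)) - 1,
    0)
  SAce <- SAbund + SRare / CAce + (n1 / CAce) * gammaSq
  new("AceComponents", abund = abund, SRare = SRare, SAbund = SAbund,
      NRare = NRare, CAce = CAce, gammaSq = gammaSq, SAce = SAce)
})

#' @rdname ace
#' @export
setMethod("ace", "OTUAssignment",
          function(x, abund = 10L) ace(sizeProfile(x), abund = abund))

#' @param components an [AceComponents-class].
#' @rdname ace
#' @export
aceEstimate <- function(components) components@SAce

#' Per-sample diversity summary table
#'
#' One row per sample of a (possibly joint) assignment: sequence count,
#' observed OTUs and the three estimators — the standard report columns of
#' amplicon diversity studies.
#'
#' @param assignment an [OTUAssignment-class].
#' @param abund ACE rare/abundant threshold (default 10).
#' @return a data.frame with columns \code{sample_id}, \code{N},
#'   \code{S_obs}, \code{chao1}, \code{shannon}, \code{ace} (\code{ace} is
#'   \code{NA} where the estimator is undefined).
#' @export
diversityTable <- function(assignment, abund = 10L) {
  bySample <- split(assignment@labels, assignment@sample)
  rows <- lapply(names(bySample), function(s) {
    prof <- sizeProfile(as.integer(table(bySample[[s]])))
    aceVal <- tryCatch(aceEstimate(ace(prof, abund = abund)),
                       error = function(e) NA_real_)
    data.frame(sample_id = s, N = prof@N, S_obs = prof@SObs,
               chao1 = chao1(prof), shannon = shannon(prof), ace = aceVal)
  })
  do.call(rbind, rows)
}
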