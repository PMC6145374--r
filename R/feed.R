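#' Specify a feeding condition
#'
#' A feed fixes the boundary conditions of an experiment: the normalized
#' level and 13C9-label fraction of the two amino-acid sources, and optional
#' unlabeled medium additions of cinnamic acid and *p*-coumaric acid
#' (zero-order influxes into the cytosolic CA and pCA pools, as in the
#' dilution experiments).
#'
#' Source levels are multiplies of the wild-type normalized value 100; label
#' fractions are in [0, 1]. Medium additions are constant influx rates in
#' cytosol-local normalized flux units with label fraction 0.
#'
#' @param phe_label,tyr_label label fraction of the phenylalanine and
#'   tyrosine supply
#' @param phe_scale,tyr_scale source level relative to wild type (1 = WT)
#' @param ca_influx,pca_influx unlabeled medium influx of cinnamic acid /
#'   *p*-coumaric acid
#' @return object of class `feed_spec`
#' @export
feed_spec <- function(phe_label = 0, tyr_label = 0,
                      phe_scale = 1, tyr_scale = 1,
                      ca_influx = 0, pca_influx = 0) {
  stopifnot(phe_label >= 0, phe_label <= 1, tyr_label >= 0, tyr_label <= 1,
            phe_scale >= 0, tyr_scale >= 0, ca_influx >= 0, pca_influx >= 0)
  structure(list(phe_label = phe_label, tyr_label = tyr_label,
                 phe_scale = phe_scale, tyr_scale = tyr_scale,
                 ca_influx = ca_influx, pca_influx = pca_influx),
            class = "feed_spec")
}

# label fraction of a source metabolite under a feed
source_label <- function(feed, metabolite) {
  if (metabolite == 1L) feed$phe_label else if (metabolite == 3L)
    feed$tyr_label else stop("not a source metabolite: ", metabolite)
}

source_level <- function(feed, metabolite) {
  100 * if (metabolite == 1L) feed$phe_scale else if (metabolite == 3L)
    feed$tyr_scale else stop("not a source metabolite: ", metabolite)
}

# medium influxes as a named vector over (metabolite id, cytosol) targets
medium_influxes <- function(feed) {
  c(`2` = feed$ca_influx, `4` = feed$pca_influx)
}
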