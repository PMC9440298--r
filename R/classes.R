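#' Ecosystem classes
#'
#' The accounting scheme covers exactly nine ecosystem classes: two woodland
#' classes (forest, shrub), three grassland coverage classes and four aquatic
#' classes. Each class is either terrestrial or aquatic; the river class is
#' the only one carrying materials-transport and hydropower services.
#'
#' @return A data.frame with one row per class: `code` (F1, F2, G1, G2, G3,
#'   A1, A2, A3, A4), `label`, and logical flags `terrestrial`, `aquatic`,
#'   `river`.
#' @examples
#' es_classes()
#' @export
es_classes <- function() {
  data.frame(
    code = c("F1", "F2", "G1", "G2", "G3", "A1", "A2", "A3", "A4"),
    label = c(
      "forest", "shrub",
      "high-coverage grassland", "medium-coverage grassland",
      "low-coverage grassland",
      "wetland", "lake", "reservoir/pond", "river"
    ),
    terrestrial = c(rep(TRUE, 5), rep(FALSE, 4)),
    aquatic = c(rep(FALSE, 5), rep(TRUE, 4)),
    river = c(rep(FALSE, 8), TRUE),
    stringsAsFactors = FALSE
  )
}

#' @rdname es_classes
#' @param code character vector of class codes.
#' @export
is_terrestrial <- function(code) {
  cls <- es_classes()
  stopifnot(all(code %in% cls$code))
  cls$terrestrial[match(code, cls$code)]
}

#' @rdname es_classes
#' @export
is_aquatic <- function(code) !is_terrestrial(code)

#' @rdname es_classes
#' @export
is_river <- function(code) {
  stopifnot(all(code %in% es_classes()$code))
  code == "A4"
}

#' Service applicability matrix
#'
#' Not every service is provided by every ecosystem class. Terrestrial
#' classes carry NPP, carbon sequestration (CS), soil building (SB),
#' groundwater recharge (GR), air purification (AP), soil retention (SR),
#' microclimate regulation (MR) and climate regulation (CR). Non-river
#' aquatic classes replace SB/SR with sediment building (SBa) and water
#' purification (WP). Rivers additionally carry materials transport (MT) and
#' hydropower potential (HG).
#'
#' @return A logical matrix, classes in rows, services in columns.
#' @export
service_applicability <- function() {
  services <- c("npp", "cs", "sb", "sba", "gr", "ap", "wp",
                "sr", "mr", "mt", "hg", "cr")
  cls <- es_classes()
  m <- matrix(FALSE, nrow = nrow(cls), ncol = length(services),
              dimnames = list(cls$code, services))
  terrestrial <- cls$code[cls$terrestrial]
  aquatic_nr <- cls$code[cls$aquatic & !cls$river]
  m[terrestrial, c("npp", "cs", "sb", "gr", "ap", "sr", "mr", "cr")] <- TRUE
  m[aquatic_nr, c("npp", "cs", "sba", "gr", "ap", "wp", "mr", "cr")] <- TRUE
  m["A4", c("npp", "cs", "sba", "gr", "ap", "wp", "mr", "mt", "hg", "cr")] <- TRUE
  m
}

#' @rdname service_applicability
#' @param code class code(s).
#' @param service service key(s), lowercase (e.g. "sb", "wp").
#' @export
service_applies <- function(code, service) {
  m <- service_applicability()
  stopifnot(all(code %in% rownames(m)), all(service %in% colnames(m)))
  m[cbind(code, service)]
}
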