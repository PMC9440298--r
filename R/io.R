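# CSV readers/writers. Numbers are serialized with 17 significant digits
# ("%.17g"), which round-trips IEEE doubles exactly, so read(write(x)) == x
# for every table.

#' Write and read pipeline tables
#'
#' All pipeline tables (records, dams, region, cognition, areas, ledgers,
#' totals, attribution, reports) travel as plain CSV with fixed headers and
#' full-precision numbers. [write_table()] serializes numeric columns with
#' 17 significant digits so a write/read cycle reproduces every double
#' bit-for-bit; [read_table()] restores numeric, logical and character
#' columns.
#'
#' @param x data.frame to write.
#' @param path CSV file path.
#' @return [write_table()]: `path` invisibly; [read_table()]: a data.frame.
#' @export
write_table <- function(x, path) {
  y <- x
  for (cl in names(y)) {
    if (is.numeric(y[[cl]]))
      y[[cl]] <- ifelse(is.na(y[[cl]]), "", sprintf("%.17g", y[[cl]]))
    else if (is.logical(y[[cl]]))
      y[[cl]] <- ifelse(is.na(y[[cl]]), "", ifelse(y[[cl]], "TRUE", "FALSE"))
  }
  utils::write.csv(y, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character", check.names = FALSE)
  for (cl in names(x)) {
    v <- x[[cl]]
    v[v == ""] <- NA
    if (all(is.na(v) | v %in% c("TRUE", "FALSE"))) {
      x[[cl]] <- as.logical(v)
    } else {
      num <- suppressWarnings(as.numeric(v))
      if (all(is.na(num) == is.na(v))) x[[cl]] <- num else x[[cl]] <- v
    }
  }
  x
}

#' Service ledger in long form
#'
#' Converts the wide per-record ledger to the exchange layout with one row
#' per (unit, class, epoch, service, component); `component` is `"total"`
#' for the service value itself and a named part (`hh`, `eq`, `organic`,
#' `mineral`, `rain`, `mountain`) for the stored sub-components.
#' Non-applicable services are absent rows, never zeros.
#'
#' @param ledger wide ledger from [compute_services()].
#' @return long-form data.frame: `unit_id`, `ecosystem`, `epoch`,
#'   `service`, `component`, `value`.
#' @export
ledger_to_long <- function(ledger) {
  parts <- list(
    npp = c(total = "npp"),
    cs = c(total = "cs"),
    sb = c(total = "sb", organic = "sb_organic", mineral = "sb_mineral"),
    sba = c(total = "sba"),
    gr = c(total = "gr"),
    ap = c(total = "ap", hh = "ap_hh", eq = "ap_eq"),
    wp = c(total = "wp", hh = "wp_hh", eq = "wp_eq"),
    sr = c(total = "sr"),
    mr = c(total = "mr"),
    mt = c(total = "mt"),
    hg = c(total = "hg", rain = "hg_rain", mountain = "hg_mountain"),
    cr = c(total = "cr", hh = "cr_hh", eq = "cr_eq"))
  out <- list()
  for (svc in names(parts)) {
    for (comp in names(parts[[svc]])) {
      col <- parts[[svc]][[comp]]
      keep <- !is.na(ledger[[col]])
      if (!any(keep)) next
      out[[length(out) + 1]] <- data.frame(
        unit_id = ledger$unit_id[keep], ecosystem = ledger$ecosystem[keep],
        epoch = ledger$epoch[keep], service = svc, component = comp,
        value = ledger[[col]][keep], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$unit_id, res$ecosystem, res$epoch, res$service,
            res$component), , drop = FALSE]
}
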