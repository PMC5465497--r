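#' IMGT C-DOMAIN position labels
#'
#' Immunoglobulin constant domains are compared across classes (and across
#' antibodies and T-cell receptors) through the IMGT unique numbering for
#' C-DOMAIN, which labels structurally equivalent positions with the same
#' number.  Labels are either plain integers (`"84"`) or carry a decimal
#' insertion suffix (`"84.2"`, `"85.1"`).  These helpers parse, render and
#' order such labels.
#'
#' The chain order of inserted positions follows the C-DOMAIN convention for
#' the loop between the F and G strands: positions `84.x` ascend away from 84
#' and positions `85.x` descend into 85, so that
#' `84 < 84.1 < 84.2 < ... < 85.2 < 85.1 < 85`.  Decimal labels anchored on
#' any other number sort ascending after their anchor.
#'
#' @param x character vector of position labels.
#' @return `imgt_parse()` returns a data.frame with integer columns `main`
#'   and `sub` (`sub` is `NA` for plain positions); `imgt_key()` a numeric
#'   sort key implementing the chain order; `imgt_sort()` the labels in chain
#'   order.
#' @examples
#' imgt_sort(c("85", "84.2", "85.1", "84", "90"))
#' @export
imgt_parse <- function(x) {
  x <- as.character(x)
  ok <- grepl("^[0-9]+(\\.[0-9]+)?$", x)
  if (any(!ok)) {
    stop("malformed IMGT position label(s): ",
         paste(unique(x[!ok]), collapse = ", "))
  }
  main <- as.integer(sub("\\..*$", "", x))
  sub_ <- rep(NA_integer_, length(x))
  has <- grepl("\\.", x)
  sub_[has] <- as.integer(sub("^[0-9]+\\.", "", x[has]))
  if (any(main < 1L) || any(!is.na(sub_) & sub_ < 1L)) {
    stop("IMGT position components must be positive")
  }
  data.frame(main = main, sub = sub_)
}

#' @rdname imgt_parse
#' @param main,sub integer components as returned by [imgt_parse()].
#' @export
imgt_format <- function(main, sub = NA_integer_) {
  ifelse(is.na(sub), as.character(main), paste0(main, ".", sub))
}

# Anchors whose decimal insertions sort *before* the anchor (descending).
.before_anchors <- 85L

#' @rdname imgt_parse
#' @export
imgt_key <- function(x) {
  p <- imgt_parse(x)
  key <- p$main * 1000
  ins <- !is.na(p$sub)
  dir <- ifelse(p$main %in% .before_anchors, -1, 1)
  key[ins] <- key[ins] + dir[ins] * p$sub[ins]
  key
}

#' @rdname imgt_parse
#' @export
imgt_sort <- function(x) x[order(imgt_key(x))]

#' Interface positions of Ig constant-domain dimers
#'
#' The fifteen IMGT C-DOMAIN positions that carry the interdomain
#' protein-protein interface of Ig constant-domain homo- and heterodimers
#' (beta-strand positions shared by antibody CH3/CH4 pairs and TCR constant
#' domain pairs), in chain order.
#'
#' @return character vector of 15 IMGT position labels.
#' @examples
#' interface_positions()
#' @export
interface_positions <- function() {
  c("3", "5", "7", "20", "22", "26", "27", "79", "81",
    "84", "84.2", "85.1", "86", "88", "90")
}

#' Interface catalog with design-role annotations
#'
#' Annotates the interface position set with the roles used when exchanging
#' interfaces: four key sets of reciprocal positions that break the symmetry
#' of a homodimeric interface (position 88 of one chain packing against
#' 85.1/86 of the other, and position 20 against 26), the supporting
#' positions that accommodate them, and the two-sided partition used for
#' half-interface (mixed interface, MI) grafting between two homodimers.
#'
#' @return a list with elements `positions`, `key_sets` (list of four, each
#'   with `chain_a` and `chain_b` position vectors), `supporting`,
#'   `half_side_1` and `half_side_2`.
#' @export
interface_catalog <- function() {
  list(
    positions = interface_positions(),
    key_sets = list(
      set1 = list(chain_a = "88", chain_b = c("85.1", "86")),
      set2 = list(chain_b = "88", chain_a = c("85.1", "86")),
      set3 = list(chain_a = "20", chain_b = "26"),
      set4 = list(chain_b = "20", chain_a = "26")
    ),
    supporting = c("3", "5", "7", "22", "79", "81", "84", "84.2", "90"),
    half_side_1 = c("20", "79", "81", "88", "90"),
    half_side_2 = c("3", "5", "26", "84", "84.2", "85.1", "86")
  )
}
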