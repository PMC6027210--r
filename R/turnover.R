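#' Sex-bias direction turnover between two stages/tissues
#'
#' Shared genes are those called sex-biased in both classes. A turnover is a
#' shared gene whose direction switches (female-biased in A and male-biased
#' in B, or the reverse). The reported proportion is
#' (f2m + m2f) / shared, also given rounded to a whole percent.
#'
#' @param bias_a,bias_b per-gene records from \code{\link{call_sex_bias}} for
#'   the two classes.
#' @return list \code{pair, n_shared, n_f2m, n_m2f, proportion,
#'   percent, reportable} where \code{reportable} marks pairs with more than
#'   \code{shared_min} shared sex-biased genes.
#' @param shared_min pairs with \code{n_shared} strictly greater than this
#'   qualify for reporting (default 35).
#' @export
turnover_summary <- function(bias_a, bias_b, shared_min = 35) {
  a <- bias_a[bias_a$biased, c("gene_id", "direction")]
  b <- bias_b[bias_b$biased, c("gene_id", "direction")]
  m <- merge(a, b, by = "gene_id", suffixes = c("_a", "_b"))
  n_shared <- nrow(m)
  n_f2m <- sum(m$direction_a == "female" & m$direction_b == "male")
  n_m2f <- sum(m$direction_a == "male" & m$direction_b == "female")
  if (n_shared == 0) {
    warning("no shared sex-biased genes; turnover proportion undefined")
    prop <- NA_real_
  } else {
    prop <- (n_f2m + n_m2f) / n_shared
  }
  list(pair = c(bias_a$class[1], bias_b$class[1]),
       n_shared = n_shared, n_f2m = n_f2m, n_m2f = n_m2f,
       proportion = prop,
       percent = if (is.na(prop)) NA_real_ else round(100 * prop),
       reportable = n_shared > shared_min)
}

#' Consistency classes of shared sex-biased genes
#'
#' Partitions genes sex-biased in both classes into consistently male-biased,
#' consistently female-biased, and turnover (direction switch).
#'
#' @inheritParams turnover_summary
#' @return data.frame \code{gene_id, consistency} with consistency in
#'   \code{consistent_male, consistent_female, turnover}.
#' @export
consistency_classes <- function(bias_a, bias_b) {
  a <- bias_a[bias_a$biased, c("gene_id", "direction")]
  b <- bias_b[bias_b$biased, c("gene_id", "direction")]
  m <- merge(a, b, by = "gene_id", suffixes = c("_a", "_b"))
  cls <- ifelse(m$direction_a != m$direction_b, "turnover",
                ifelse(m$direction_a == "male", "consistent_male",
                       "consistent_female"))
  data.frame(gene_id = m$gene_id, consistency = cls,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare a per-gene quantity between gene classes
#'
#' Two-sided Wilcoxon rank-sum tests for each pair of classes (no multiplicity
#' correction; raw p-values are reported), plus per-class medians. Classes
#' with fewer than two members are skipped with a message.
#'
#' @param values named numeric vector (names = gene ids) of the quantity
#'   compared, e.g. dN/dS or Tau; NAs dropped.
#' @param classes data.frame \code{gene_id, consistency} (or any second
#'   column giving the class label).
#' @return list with \code{medians} (named vector) and \code{tests}
#'   (data.frame \code{class_a, class_b, n_a, n_b, pvalue}).
#' @export
class_compare <- function(values, classes) {
  lab <- classes[[2L]]
  v <- values[classes$gene_id]
  ok <- !is.na(v)
  v <- v[ok]; lab <- lab[ok]
  if (!length(v)) stop("no usable values in any class")
  groups <- split(v, lab)
  medians <- vapply(groups, median, numeric(1))
  nm <- names(groups)
  tests <- NULL
  if (length(nm) >= 2L) {
    for (i in seq_len(length(nm) - 1L)) for (j in seq((i + 1L), length(nm))) {
      ga <- groups[[i]]; gb <- groups[[j]]
      if (length(ga) < 2L || length(gb) < 2L) {
        message("class with <2 members, skipping comparison ",
                nm[i], " vs ", nm[j])
        next
      }
      p <- suppressWarnings(stats::wilcox.test(ga, gb)$p.value)
      tests <- rbind(tests, data.frame(class_a = nm[i], class_b = nm[j],
                                       n_a = length(ga), n_b = length(gb),
                                       pvalue = p, stringsAsFactors = FALSE))
    }
  }
  list(medians = medians, tests = tests)
}
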