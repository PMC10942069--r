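#' Life tables
#'
#' A `life_table` is a data.frame with integer column `age` (contiguous,
#' strictly increasing by one year) and numeric column `qx`, the annual
#' probability of death from all causes at that age. Lookups beyond the last
#' tabulated age return `qx = 1`.
#'
#' @param age integer ages.
#' @param qx annual death probabilities in `[0, 1]`.
#' @return a `life_table` data.frame.
#' @export
life_table <- function(age, qx) {
  lt <- data.frame(age = as.integer(age), qx = as.numeric(qx))
  class(lt) <- c("life_table", "data.frame")
  validate_life_table(lt)
  lt
}

#' @rdname life_table
#' @param lt object to validate.
#' @export
validate_life_table <- function(lt) {
  if (!all(c("age", "qx") %in% names(lt))) stop("life table needs columns 'age' and 'qx'")
  if (nrow(lt) < 1) stop("life table is empty")
  if (any(diff(lt$age) != 1)) stop("life table ages must be contiguous (step 1)")
  if (any(lt$qx < 0 | lt$qx > 1 | is.na(lt$qx))) stop("'qx' values must lie in [0, 1]")
  invisible(lt)
}

#' Annual death probability at a given age
#'
#' @param lt a `life_table`.
#' @param age age in whole years (vectorised).
#' @return `qx` at `age`; 1 beyond the table, error below it.
#' @export
qx_at <- function(lt, age) {
  if (any(age < lt$age[1])) stop("age below the first tabulated age")
  i <- age - lt$age[1] + 1
  out <- rep(1, length(age))
  inside <- i <= nrow(lt)
  out[inside] <- lt$qx[i[inside]]
  out
}

#' Read / write a life table as delimited text
#'
#' Tab-delimited with a header row `age<TAB>qx`.
#'
#' @param path file path.
#' @return [read_life_table()] returns a validated `life_table`.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("life table file not found: ", path)
  df <- utils::read.delim(path, header = TRUE)
  life_table(df$age, df$qx)
}

#' @rdname read_life_table
#' @param lt a `life_table`.
#' @export
write_life_table <- function(lt, path) {
  validate_life_table(lt)
  utils::write.table(as.data.frame(lt), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
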