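# Mandatory (Type-1) tags per exported object type.  A query that comes
# back empty for one of these flags the dataset INCOMPLETE (it is still
# exportable under the lenient policy, with the failure accounted for);
# anything else missing only logs a warning.

.type1 <- list(
  CT = c("00080016", "00080018", "00100020", "0020000D", "0020000E",
         "00200052", "7FE00010"),
  MVCT = c("00080016", "00080018", "00100020", "0020000D", "0020000E",
           "00200052", "7FE00010"),
  RTPLAN = c("00080016", "00080018", "00100020", "0020000D", "0020000E",
             "300A0002"),
  RTDOSE = c("00080016", "00080018", "00100020", "0020000D", "0020000E",
             "3004000E", "7FE00010"),
  QADOSE = c("00080016", "00080018", "00100020", "0020000D", "0020000E",
             "3004000E", "7FE00010"),
  RTSTRUCT = c("00080016", "00080018", "00100020", "0020000D", "0020000E",
               "30060002"),
  DELIVERY_SINOGRAM = c("00080016", "00080018", "00100020", "0020000D",
                        "0020000E", "7FE00010"),
  RTRECORD = c("00100010", "0020000D", "0020000E")
)

#' Mandatory tags for an object type
#' @param target_type One of the supported object variants.
#' @return Character vector of `"GGGGEEEE"` tags.
#' @export
mandatory_tags <- function(target_type) {
  .type1[[target_type]] %||% character(0)
}
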