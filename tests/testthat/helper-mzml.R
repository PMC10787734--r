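# Minimal mzML writer (64-bit float, no compression) for read-back tests.
write_test_mzml <- function(mass, intensity, path) {
  enc <- function(x)
    gsub("\n", "", jsonlite::base64_enc(writeBin(as.double(x), raw(),
                                                 size = 8,
                                                 endian = "little")),
         fixed = TRUE)
  bda <- function(x, acc, nm) {
    e <- enc(x)
    paste0('<binaryDataArray encodedLength="', nchar(e), '">',
           '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
           '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
           '<cvParam cvRef="MS" accession="', acc, '" name="', nm, '" value=""/>',
           '<binary>', e, '</binary></binaryDataArray>')
  }
  xml <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="1"><cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/></cvList>\n',
    '<run id="run1">\n<spectrumList count="1">\n',
    '<spectrum index="0" id="scan=1" defaultArrayLength="', length(mass), '">\n',
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>\n',
    '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>\n',
    '<binaryDataArrayList count="2">', bda(mass, "MS:1000514", "m/z array"),
    "\n", bda(intensity, "MS:1000515", "intensity array"),
    '\n</binaryDataArrayList></spectrum></spectrumList></run></mzML>')
  writeLines(xml, path)
  invisible(path)
}
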