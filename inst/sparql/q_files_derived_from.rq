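# Files (output plots) that saved data derived from an input file
PREFIX neao_base: <http://purl.org/neao/base#>
PREFIX prov: <http://www.w3.org/ns/prov#>
PREFIX cap: <http://example.org/capture#>
PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
SELECT DISTINCT ?src ?out
WHERE {
  ?srcfile cap:fileEventKind "read" .
  ?srcfile cap:filePath ?src .
  ?srcfile (^prov:used|prov:generated|prov:hadMember)+ ?outfile .
  ?outfile cap:fileEventKind "write" .
  ?outfile cap:filePath ?out .
}
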