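# AnalysisStep classes on the derivation chain of each saved file
PREFIX neao_base: <http://purl.org/neao/base#>
PREFIX prov: <http://www.w3.org/ns/prov#>
PREFIX cap: <http://example.org/capture#>
PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
SELECT DISTINCT ?path ?class
WHERE {
  ?f cap:fileEventKind "write" .
  ?f cap:filePath ?path .
  ?e (prov:generated|prov:hadMember|^prov:used)+ ?f .
  ?e a cap:FunctionExecution .
  ?e a ?class .
  ?class rdfs:subClassOf neao_base:AnalysisStep .
}
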