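>Hs
DHTWLLYEPVVLWHQTDGYALYHRAKGNIKNGGKDVNKGNAKHDQTETFCNFIFWDEERKGSQPHQISFVTVRDKCNEEY
CFMDQTEWIKWEGMFLIFTDFMRFIMHEYCMQCHGPSGIFKFCLKTIVKEPCKIMRKPTREPIEMTSILLFVIWKNMWTF
RCQANWQFRKSLQIENPDRTIFICKRIAHINHRGHPEWGP
>Tb
DHIWLLYEPVVLWTQDDGYALYHRAKGNIKNGGKDVGKGSAKHDQTETFRNFIFWDEERKGSQPHQISFVTPRDKCNEEY
CFMGQTEWIKTEGMFLISTWQMMFIMHEYCMQNHGPTGIFKFCLKTIVKEPCKIMRKPTREPDEQTSILLFVIWKNMWTF
RCQANWQFVKSCMIENPNRTIFICKRIAHINHRGHNEWNP
>Ts
DHTWLLYEPVVLWHCTDGYALYHRAKGNIKNGGKDVNKGNAKHDQPETVCNFIFWDEERKGSQPHQISFVTVRDKCNEVY
CVMDQTEWIKWEGMFLIFTDFMRFVSHEYCMQCHGPSGIFKFCLKTIVKEPCKIMLKPTREPIAMTSKLLFVIWKNVWTQ
RCQANYQFRKSLQIENPDRTIFICKRIAHIFHRGHLEWGP
>Dm
DHTWLNYEGVTLWHQTDGWILYHRAKGNIKNGGKDVNKGNAKHDQTETFCNFIFWDEERKGSQPHQIAFVTVRDKCNYQY
CFGDQTEWIKWEGMFLIETDFNKFIMHEYCMQCHGPSGIIKFCLKTIVKEPCKIMRKPTREPIEMTSILLFVIWKNMWTF
RCYARWQFRKSQQIDNPDRTIFICKRIIHINHWGIPEWGP
>Af
DHTWLLYEPVVLWHQTDGYALYHRAKGNIKNGGKDVNKGNAKHDQTETFCNFIFWDSERKGSQPHQISERTVRDKCNEEY
CFMDQTEWIKWTGMFLIFTDFMRFIMHEYCMQCHGPSGIFKFCLKTIVKEPCKIMRKPTREPIEMTPILLFVEWKNMWTF
RCQANWQQRKSLQIENPDRTIDIRKRIAHISHFGHPEIGP
>Ec
DHTWLTYEPVVLWHQTDGYALYHRAKGNIKNGGKDVNKRNAKYDQTKTFCSFIFWDEERKGLQPHQISFVTVRDKCNVEY
CKMYQWEWGKWERMFLIFRDFMRFIMHEYCMQCHGPSGIFKFCLKTIVKEPCKIMRKPTREPDEMQSVLLFVIWKNMIPF
RCQANWQFRKLLQIENPDRTYFICKRIAHINHRGHPEWHP
>At
DHTWLLREPWVLWHQTDGYALYHRAKGNYKNGGKEVNKGNAKHDQTETFCNFIFWDGERKGSQPHQQSFVTVRDKCNEEY
CFMDQTDWIKWEGMFLIFTDFMRFIMHEYMMQCHGPSGHFKFCLKTIVKEPCKILGKPTREPIEMTSILLAVIWKNMWGF
RCQANWQFRKSLQIENPSRTIFICKRDAHIYHRGDPEWGP
>Dr
DHTWLMYEPVKLWHQTDGYALYHCAKGNIKNGGKDVNKGNAKHDQTETFCQFIFWDEENKGSQPHQISFVTVRDKCNEWY
CFTDQTRWIKWEGMFLIFTDFMRFIMHEYHVQCHGPKGIFKFCLKTIVKEPCKIMRKPTREPIEMTSINLFVIWKNMWTG
RCQANWQFRKSLQSENPDRTIFICKRIAHIPHRIHPWWGP
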