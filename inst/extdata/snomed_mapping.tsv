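cui	snomed_code
C0011854	73211009
C0011860	44054006
C0004096	195967001
C0155877	389145006
C0020538	38341003
C0007102	363406005
C0006826	363346000
C0006142	254837009
C0038454	230690007
C0027051	22298006
C0011570	35489007
C0036572	91175000
C0149931	37796009
C0028754	414916001
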