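>EUTX-Ei1
MVKQLVAAFLVIMLISSLVDAKKTFMEKAKSVFSKAGNKIKEIAGKSEYMCPVVSSFCEQHCARQEKSGECDFNKCTCS
>EUTX-Ei2a
MNAKLTVLLFLAMVAIASCGWINEKRVQSYIDEKIPNGVMKGAIKAVVHKIAKNEYGCVANIDTVSQCNKHCIAAGSEKGVCHGTKCKCDKELSYRRK
>EUTX-Ei2b
MQIRCSILLLLMISSFCSCGILREKYFHQAVDKVAPMIPLPVVSQVVGNVAKQIVHKFAKNEALCMFNKDVAGMCDKSCKEAGKSNGICHGTKCKCDKPLSYKKK
>EUTX-Ei3a
MKRLQVAALVCLLLCALFSLSAGAGEICEANGLSIPVGQDKQDPKSCDLYKCIMQNNRLVLDKFSCATLKRKRGCKIVPGDSKAAFPKCCPTSNCRGAQWDQ
>EUTX-Ei3b
MENALGGVMLGSLLLLSLFSASLAIGEKCETGQHVI[D/E]VGKQVQDSKSCTLYKCINYNRKYALETLTCASQKLKSGCRSIPGAANTPFPNCCPTVICQG
>AMP-Ei1
MHFNKTLLVIFLSYLLVTDEAEAFWGFLAKLATKVVPSLFGSSSEKSKREIENFFEPYQKDLDLELDRFDRFLSKLDLN
>AMP-Ei2a
MKNQFVILIIAVVLLQLFSPSEAILSDIWNGIKGLFGKRGLFPQRPLINRDQFDDVFDDDLSAADLKFLQELLK
>AMP-Ei2b
MKNQFVILVIAVVLLQLFSPSEAILSDIWNGIKSIFGKRGLRNLDRFDDLFDDDVSDADLKVLQELFR
>NVC-Ei1
MKCYLAVLVLLLVCAVLPDQTCGIENGRKSPNFCRNKCLKEYIPNNCVGYCERVLKEKE[K/E]KEG
>EUTX-Ei4
MKWCTVFMFCLVILVHEFQDVYGEKEGYPLDATRNIYQCYDLGENDYCEKKCKEFGGHGYCYGFACYCKYIRDDVKIWKG
>PI-Ei1a
MTNLRETVANMKTLAVTLLTLAAFQLVLPYPQPEESSPPENCGENELFYGRRTCAPICNDEVCKKPSREPTACFAICYQGCYCKEGYGRNRRNETCVKCE
>EUTX-Ei5
MNLIIIFTLLLSSPFIEVEGSQVNARASCTNSGVCRSSTCPSRGCRSGKCINRKCTCYYC
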