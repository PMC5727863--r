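<?xml version="1.0" encoding="UTF-8"?>
<bpmn:definitions xmlns:bpmn="http://www.omg.org/spec/BPMN/20100524/MODEL" xmlns:cf="urn:checkflow:bpmn-ext" id="defs_pci" targetNamespace="urn:checkflow:models">
  <bpmn:process id="pci" name="PCI peri-operative care pathway" isExecutable="true">
    <bpmn:laneSet id="pci_lanes">
      <bpmn:lane id="lane_cardiologist" name="Interventional cardiologist">
        <bpmn:flowNodeRef>perform_pci</bpmn:flowNodeRef>
        <bpmn:flowNodeRef>extended_monitoring</bpmn:flowNodeRef>
        <bpmn:flowNodeRef>discharge</bpmn:flowNodeRef>
      </bpmn:lane>
      <bpmn:lane id="lane_cath_nurse" name="Catheterisation-lab nurse">
        <bpmn:flowNodeRef>admission</bpmn:flowNodeRef>
        <bpmn:flowNodeRef>preop_preparation</bpmn:flowNodeRef>
      </bpmn:lane>
      <bpmn:lane id="lane_technician" name="Radiology technician">
        <bpmn:flowNodeRef>equipment_check</bpmn:flowNodeRef>
      </bpmn:lane>
    </bpmn:laneSet>
    <bpmn:startEvent id="start"/>
    <bpmn:userTask id="admission" name="Admit patient to the catheterisation lab">
      <bpmn:potentialOwner>
        <bpmn:resourceRef>cath_nurse</bpmn:resourceRef>
      </bpmn:potentialOwner>
    </bpmn:userTask>
    <bpmn:parallelGateway id="ps1"/>
    <bpmn:userTask id="preop_preparation" name="Pre-operative preparation">
      <bpmn:extensionElements>
        <cf:safetyGuard form="pci_preop" trigger="on_entry"/>
        <cf:safetyGuard form="pci_preop" trigger="overdue" overdueAfter="120"/>
      </bpmn:extensionElements>
      <bpmn:potentialOwner>
        <bpmn:resourceRef>cath_nurse</bpmn:resourceRef>
      </bpmn:potentialOwner>
    </bpmn:userTask>
    <bpmn:userTask id="equipment_check" name="Check imaging and contrast equipment">
      <bpmn:potentialOwner>
        <bpmn:resourceRef>technician</bpmn:resourceRef>
      </bpmn:potentialOwner>
    </bpmn:userTask>
    <bpmn:parallelGateway id="pj1"/>
    <bpmn:userTask id="perform_pci" name="Perform percutaneous coronary intervention">
      <bpmn:extensionElements>
        <cf:safetyGuard form="pci_timeout" trigger="on_entry"/>
      </bpmn:extensionElements>
      <bpmn:potentialOwner>
        <bpmn:resourceRef>cardiologist</bpmn:resourceRef>
      </bpmn:potentialOwner>
    </bpmn:userTask>
    <bpmn:exclusiveGateway id="xs1" default="e9"/>
    <bpmn:userTask id="extended_monitoring" name="Extended post-procedural monitoring">
      <bpmn:potentialOwner>
        <bpmn:resourceRef>cardiologist</bpmn:resourceRef>
      </bpmn:potentialOwner>
    </bpmn:userTask>
    <bpmn:exclusiveGateway id="xm1"/>
    <bpmn:userTask id="discharge" name="Discharge and follow-up planning">
      <bpmn:potentialOwner>
        <bpmn:resourceRef>cardiologist</bpmn:resourceRef>
      </bpmn:potentialOwner>
    </bpmn:userTask>
    <bpmn:endEvent id="end"/>
    <bpmn:sequenceFlow id="e1" sourceRef="start" targetRef="admission"/>
    <bpmn:sequenceFlow id="e2" sourceRef="admission" targetRef="ps1"/>
    <bpmn:sequenceFlow id="e3" sourceRef="ps1" targetRef="preop_preparation"/>
    <bpmn:sequenceFlow id="e4" sourceRef="ps1" targetRef="equipment_check"/>
    <bpmn:sequenceFlow id="e5" sourceRef="preop_preparation" targetRef="pj1"/>
    <bpmn:sequenceFlow id="e6" sourceRef="equipment_check" targetRef="pj1"/>
    <bpmn:sequenceFlow id="e7" sourceRef="pj1" targetRef="perform_pci"/>
    <bpmn:sequenceFlow id="e7b" sourceRef="perform_pci" targetRef="xs1"/>
    <bpmn:sequenceFlow id="e8" sourceRef="xs1" targetRef="extended_monitoring">
      <bpmn:conditionExpression>complication == true</bpmn:conditionExpression>
    </bpmn:sequenceFlow>
    <bpmn:sequenceFlow id="e9" sourceRef="xs1" targetRef="xm1"/>
    <bpmn:sequenceFlow id="e10" sourceRef="extended_monitoring" targetRef="xm1"/>
    <bpmn:sequenceFlow id="e11" sourceRef="xm1" targetRef="discharge"/>
    <bpmn:sequenceFlow id="e12" sourceRef="discharge" targetRef="end"/>
  </bpmn:process>
</bpmn:definitions>
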